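#' Read a grid-aligned bedGraph/TSV count track
#'
#' Accepts bedGraph (chrom, start, end, value; 0-based half-open) or an
#' equivalent 4-column TSV. Every interval must coincide exactly with one grid
#' window; windows absent from the file get count 0.
#'
#' @param path bedGraph/TSV file
#' @param grid the `window_grid` the track is aligned to
#' @param ... metadata passed to [count_track()] (condition, fraction, ...)
#' @return a `count_track`
#' @export
read_count_track <- function(path, grid, ...) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1
  end0 <- GenomicRanges::end(gr)
  bad <- !(chrom %in% names(grid$chromosomes))
  if (any(bad))
    stop("record ", which(bad)[1], ": unknown chromosome '",
         chrom[which(bad)[1]], "'")
  idx <- grid$offsets[chrom] + start0 %/% grid$window_size + 1
  w <- grid$windows
  misaligned <- start0 != w$start[idx] | end0 != w$end[idx]
  if (any(misaligned)) {
    i <- which(misaligned)[1]
    stop("record ", i, ": interval ", chrom[i], ":", start0[i], "-", end0[i],
         " is not aligned to a ", grid$window_size, "-bp grid window")
  }
  counts <- numeric(n_windows(grid))
  counts[idx] <- gr$score
  count_track(grid, counts, ...)
}

#' Write a track as bedGraph
#'
#' Masked windows of a `signal_track` are omitted; values keep full numeric
#' precision (>= 6 significant digits).
#'
#' @param track a `count_track` or `signal_track`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_track <- function(track, path) {
  if (inherits(track, "count_track")) {
    keep <- rep(TRUE, n_windows(track$grid))
    vals <- track$counts
  } else if (inherits(track, "signal_track")) {
    keep <- !track$mask
    vals <- track$values
  } else stop("track must be a count_track or signal_track")
  w <- track$grid$windows[keep, , drop = FALSE]
  df <- data.frame(chrom = w$chrom,
                   start = sprintf("%d", as.integer(w$start)),
                   end = sprintf("%d", as.integer(w$end)),
                   value = format(vals[keep], digits = 10, trim = TRUE,
                                  scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read interval features from BED or GFF3
#'
#' BED (0-based half-open) is taken as is; GFF3 records (1-based inclusive)
#' have their start decremented by one so everything downstream is 0-based
#' half-open. A GFF3 `expressed` attribute, when present, is carried as a
#' logical column.
#'
#' @param path BED3/BED6 or GFF3 file (format picked by extension; override
#'   with `format`)
#' @param kind feature kind label to assign ("gene", "TE", "CEN", "blacklist",
#'   ...)
#' @param format "bed" or "gff3"; default guesses from the file extension
#' @return a `feature_set`
#' @export
read_features <- function(path, kind = "custom", format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3"
    else "bed"
  }
  gr <- tryCatch(rtracklayer::import(path, format = format),
                 error = function(e)
                   stop("failed to parse ", path, ": ", conditionMessage(e)))
  start0 <- GenomicRanges::start(gr) - 1
  end0 <- GenomicRanges::end(gr)
  if (any(start0 >= end0))
    stop("interval with start >= end after coordinate conversion in ", path)
  fs <- feature_set(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                    start = start0, end = end0, kind = kind)
  md <- S4Vectors::mcols(gr)
  if ("expressed" %in% colnames(md))
    fs$expressed <- as.logical(md$expressed)
  if ("name" %in% colnames(md)) fs$name <- as.character(md$name)
  fs
}

#' Write features as BED
#' @param features a `feature_set`
#' @param path output BED file
#' @param names optional name column (defaults to `kind`)
#' @param scores optional score column (0-1000)
#' @return `path`, invisibly
#' @export
write_features <- function(features, path, names = NULL, scores = NULL) {
  df <- data.frame(chrom = features$chrom,
                   start = sprintf("%d", as.integer(features$start)),
                   end = sprintf("%d", as.integer(features$end)),
                   name = if (is.null(names)) features$kind else names,
                   score = if (is.null(scores)) 0 else round(scores),
                   strand = ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
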