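#' Fixed genome window grid
#'
#' A `window_grid` tiles every chromosome into consecutive half-open windows
#' of `window_size` bp starting at 0. It is the coordinate backbone shared by
#' all count and signal tracks: a track is simply a vector with one entry per
#' grid window, in grid order (chromosomes in the order given, windows left to
#' right). The final window of a chromosome may be shorter than `window_size`
#' when the length is not an exact multiple; such windows are kept and flagged,
#' and all statistics weight windows equally regardless of physical length.
#'
#' @param chromosomes named numeric vector of chromosome lengths in bp, in the
#'   desired order. Names are the chromosome names.
#' @param window_size window width in bp (default 3000, the replication-timing
#'   resolution; copy-number screening conventionally uses 5000).
#' @return an object of class `window_grid` with elements `chromosomes`
#'   (named lengths), `window_size`, and `windows` (data.frame with columns
#'   `chrom`, `start`, `end`, `partial`), plus per-chromosome index offsets.
#' @examples
#' g <- window_grid(c(chr1 = 10000, chr2 = 7000), window_size = 3000)
#' n_windows(g)
#' @export
window_grid <- function(chromosomes, window_size = 3000) {
  if (is.null(names(chromosomes)) || any(!nzchar(names(chromosomes))))
    stop("chromosome lengths must be named")
  if (any(chromosomes < 1)) stop("chromosome lengths must be >= 1 bp")
  if (window_size < 1) stop("window_size must be >= 1 bp")
  chromosomes <- round(chromosomes)
  nw <- ceiling(chromosomes / window_size)
  chrom <- rep(names(chromosomes), nw)
  start <- unlist(lapply(nw, function(k) (seq_len(k) - 1) * window_size),
                  use.names = FALSE)
  end <- pmin(start + window_size, rep(unname(chromosomes), nw))
  offsets <- c(0, cumsum(nw))[seq_along(nw)]
  names(offsets) <- names(chromosomes)
  structure(
    list(
      chromosomes = chromosomes,
      window_size = window_size,
      windows = data.frame(chrom = chrom, start = start, end = end,
                           partial = (end - start) < window_size,
                           stringsAsFactors = FALSE),
      offsets = offsets
    ),
    class = "window_grid"
  )
}

#' Number of windows in a grid
#' @param grid a `window_grid`
#' @return integer window count
#' @export
n_windows <- function(grid) {
  stopifnot(inherits(grid, "window_grid"))
  nrow(grid$windows)
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("window_grid: %d chromosome(s), %d bp windows, %d windows\n",
              length(x$chromosomes), x$window_size, n_windows(x)))
  invisible(x)
}

#' Map genomic positions to grid window indices
#'
#' @param grid a `window_grid`
#' @param chrom character vector of chromosome names
#' @param pos 0-based positions (bp)
#' @return integer vector of 1-based window indices into the grid
#' @export
window_index <- function(grid, chrom, pos) {
  bad <- !(chrom %in% names(grid$chromosomes))
  if (any(bad))
    stop("unknown chromosome(s): ", paste(unique(chrom[bad]), collapse = ", "))
  if (any(pos < 0) || any(pos >= grid$chromosomes[chrom]))
    stop("position outside chromosome bounds")
  as.integer(grid$offsets[chrom] + pos %/% grid$window_size + 1)
}

#' Grid windows as a GRanges
#'
#' Converts the 0-based half-open grid windows to the 1-based closed
#' convention used by GenomicRanges.
#' @param grid a `window_grid`
#' @return a `GRanges` with one range per window, in grid order
#' @export
grid_granges <- function(grid) {
  w <- grid$windows
  GenomicRanges::GRanges(
    seqnames = w$chrom,
    ranges = IRanges::IRanges(start = w$start + 1, end = w$end),
    seqinfo = GenomeInfoDb::Seqinfo(names(grid$chromosomes),
                                    unname(grid$chromosomes))
  )
}

same_grid <- function(a, b) {
  identical(a$window_size, b$window_size) &&
    identical(a$chromosomes, b$chromosomes)
}

#' Interval features (genes, TEs, centromeres, blacklist, ...)
#'
#' A `feature_set` is a data.frame of 0-based half-open intervals with a
#' `kind` label and optional attribute columns (e.g. `expressed`,
#' `superfamily`). All readers convert to this convention at the boundary
#' (BED is native; GFF3 starts are decremented by one).
#'
#' @param chrom,start,end interval coordinates (0-based half-open)
#' @param kind feature kind label, recycled (gene, TE, CEN, pericentromere,
#'   CentC, CRM, blacklist, custom, ...)
#' @param ... further attribute columns, recycled
#' @return a data.frame of class `feature_set`
#' @export
feature_set <- function(chrom = character(), start = integer(),
                        end = integer(), kind = "custom", ...) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), kind = rep_len(kind, length(chrom)),
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], nrow(df))
  if (any(df$start < 0)) stop("negative start coordinate")
  if (any(df$start >= df$end)) stop("interval with start >= end")
  class(df) <- c("feature_set", "data.frame")
  df
}

#' Convert features to GRanges (1-based closed)
#' @param features a `feature_set` or plain data.frame with chrom/start/end
#' @param grid optional `window_grid` supplying seqinfo
#' @return a `GRanges`
#' @export
features_granges <- function(features, grid = NULL) {
  si <- if (!is.null(grid))
    GenomeInfoDb::Seqinfo(names(grid$chromosomes), unname(grid$chromosomes))
  else NULL
  gr <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start + 1, end = features$end)
  )
  if (!is.null(si)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(si)
    GenomeInfoDb::seqinfo(gr) <- si
  }
  gr
}

granges_features <- function(gr, kind = "custom") {
  feature_set(chrom = as.character(GenomeInfoDb::seqnames(gr)),
              start = GenomicRanges::start(gr) - 1,
              end = GenomicRanges::end(gr),
              kind = kind)
}

# put two GRanges on the union of their seqlevels so set operations never
# complain about disjoint chromosome sets
align_seqlevels <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a = a, b = b)
}

# rbind feature sets whose attribute columns differ; missing columns get NA
bind_features <- function(lst) {
  cols <- Reduce(union, lapply(lst, names))
  out <- do.call(rbind, lapply(lst, function(df) {
    for (nm in setdiff(cols, names(df))) df[[nm]] <- NA
    df[, cols, drop = FALSE]
  }))
  class(out) <- c("feature_set", "data.frame")
  out
}

subset_features <- function(features, kinds) {
  out <- features[features$kind %in% kinds, , drop = FALSE]
  class(out) <- c("feature_set", "data.frame")
  out
}
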