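#' Randomly shuffle regions around the genome
#'
#' Each region keeps its length and is placed uniformly at random on a
#' chromosome chosen with probability proportional to placeable length,
#' wholly within the chromosome and with zero overlap of the excluded
#' intervals. Shuffled regions may land on a different chromosome and may
#' overlap one another. Regions that cannot be placed within the attempt
#' budget raise an error naming the region.
#'
#' @param regions `feature_set` to shuffle
#' @param grid a `window_grid` supplying chromosome lengths
#' @param exclude optional `feature_set` of forbidden intervals (e.g.
#'   functional centromeres)
#' @param seed integer seed
#' @param max_attempts placement attempts per region before giving up
#' @return a `feature_set` of shuffled regions (kind preserved)
#' @export
shuffle_regions <- function(regions, grid, exclude = NULL, seed = 1L,
                            max_attempts = 1000) {
  set.seed(stage_seed(seed, "shuffle"))
  chroms <- grid$chromosomes
  excl_gr <- if (!is.null(exclude) && nrow(exclude))
    GenomicRanges::reduce(features_granges(exclude))
  else GenomicRanges::GRanges()
  n <- nrow(regions)
  out_chrom <- character(n); out_start <- numeric(n)
  for (i in seq_len(n)) {
    len <- regions$end[i] - regions$start[i]
    room <- pmax(chroms - len, 0)
    if (sum(room) == 0)
      stop("region ", i, " (", len, " bp) does not fit on any chromosome")
    placed <- FALSE
    excl_chrom <- as.character(GenomeInfoDb::seqnames(excl_gr))
    excl_start0 <- GenomicRanges::start(excl_gr) - 1
    excl_end0 <- GenomicRanges::end(excl_gr)
    for (att in seq_len(max_attempts)) {
      chr <- sample(names(chroms), 1, prob = room)
      st <- floor(stats::runif(1, 0, room[[chr]] + 1))
      clash <- excl_chrom == chr & excl_start0 < st + len & excl_end0 > st
      if (!any(clash)) {
        out_chrom[i] <- chr; out_start[i] <- st; placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place region ", i, " (", regions$chrom[i], ":",
           regions$start[i], "-", regions$end[i],
           ") outside exclusions after ", max_attempts, " attempts")
  }
  feature_set(chrom = out_chrom, start = out_start,
              end = out_start + (regions$end - regions$start),
              kind = regions$kind)
}

#' Percentage of regions containing at least one feature
#'
#' @param regions,features `feature_set`s
#' @return 100 x fraction of regions overlapping >= 1 feature by >= 1 bp;
#'   NA for an empty region set
#' @export
percent_with_feature <- function(regions, features) {
  if (nrow(regions) == 0) return(NA_real_)
  if (nrow(features) == 0) return(0)
  gr <- align_seqlevels(features_granges(regions),
                        features_granges(features))
  100 * mean(IRanges::overlapsAny(gr$a, gr$b))
}

#' Percentage of region bp covered by features
#'
#' Overlapping features are flattened before measuring, so the result is
#' invariant to feature fragmentation.
#'
#' @param regions,features `feature_set`s
#' @return 100 x covered bp / total region bp; NA for empty regions
#' @export
percent_coverage <- function(regions, features) {
  if (nrow(regions) == 0) return(NA_real_)
  reg_gr <- GenomicRanges::reduce(features_granges(regions))
  total <- sum(IRanges::width(reg_gr))
  if (nrow(features) == 0) return(0)
  gr <- align_seqlevels(reg_gr,
                        GenomicRanges::reduce(features_granges(features)))
  100 * sum(IRanges::width(GenomicRanges::intersect(gr$a, gr$b))) / total
}

#' Genes overlapping each region
#'
#' @param regions,genes `feature_set`s
#' @return list with `counts` (per-region gene counts; a gene straddling
#'   two regions counts in both) and `mean`
#' @export
genes_per_region <- function(regions, genes) {
  if (nrow(regions) == 0)
    return(list(counts = integer(), mean = NA_real_))
  gr <- align_seqlevels(features_granges(regions), features_granges(genes))
  counts <- GenomicRanges::countOverlaps(gr$a, gr$b)
  list(counts = as.integer(counts), mean = mean(counts))
}

#' Permutation enrichment test by genome-wide shuffling
#'
#' Computes a statistic on the observed regions and on `n` shuffled region
#' sets that preserve the region count and size multiset. The upper-tail P
#' value is max(k, 1)/n where k counts permutations with a statistic at
#' least the observed value (so a fully extreme observation reports the
#' floor 1/n, e.g. 0.001 at 1000 shuffles); the lower tail is symmetric.
#'
#' @param regions `feature_set` of observed regions
#' @param features `feature_set` the statistic compares against
#' @param statistic function(regions, features) -> scalar (e.g.
#'   [percent_with_feature()] or [percent_coverage()])
#' @param grid a `window_grid`
#' @param exclude intervals excluded from shuffled placement
#' @param n number of permutations
#' @param seed integer seed
#' @return list of class `permutation_result`: `observed`, `permuted`,
#'   `p_upper`, `p_lower`, `n`
#' @export
permutation_test <- function(regions, features,
                             statistic = percent_with_feature, grid,
                             exclude = NULL, n = 1000, seed = 1L) {
  stopifnot(n >= 1)
  observed <- statistic(regions, features)
  permuted <- vapply(seq_len(n), function(k) {
    statistic(shuffle_regions(regions, grid, exclude,
                              seed = stage_seed(seed, paste0("perm", k))),
              features)
  }, numeric(1))
  structure(list(observed = observed, permuted = permuted,
                 p_upper = max(sum(permuted >= observed), 1) / n,
                 p_lower = max(sum(permuted <= observed), 1) / n,
                 n = n),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("permutation test: observed %.4g, null mean %.4g ",
                     "(n = %d)\n  P(>= observed) = %.4g, ",
                     "P(<= observed) = %.4g\n"),
              x$observed, mean(x$permuted), x$n, x$p_upper, x$p_lower))
  invisible(x)
}

#' Mean DRT in static windows tiled over regions
#'
#' Tiles each region with static windows (default 100 kb) and reports, per
#' window and fraction, the mean DRT over the unmasked grid windows it
#' contains; windows whose content is entirely masked report NA.
#'
#' @param drt a `drt_track`
#' @param regions `feature_set` (e.g. centromeres and pericentromeres)
#' @param window static window size in bp
#' @return data.frame: region index, chrom, start, end, mean_E, mean_M,
#'   mean_L, n_unmasked
#' @export
windowed_region_drt <- function(drt, regions, window = 100000) {
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    starts <- seq(regions$start[i], regions$end[i] - 1, by = window)
    ends <- pmin(starts + window, regions$end[i])
    for (j in seq_along(starts)) {
      idx <- region_window_indices(drt$grid, regions$chrom[i], starts[j],
                                   ends[j])
      idx <- idx[!drt$mask[idx]]
      rows[[length(rows) + 1]] <- data.frame(
        region = i, chrom = regions$chrom[i], start = starts[j],
        end = ends[j],
        mean_E = if (length(idx)) mean(drt$diffs$E[idx]) else NA_real_,
        mean_M = if (length(idx)) mean(drt$diffs$M[idx]) else NA_real_,
        mean_L = if (length(idx)) mean(drt$diffs$L[idx]) else NA_real_,
        n_unmasked = length(idx))
    }
  }
  do.call(rbind, rows)
}

#' Fraction of region windows with compensated DRT
#'
#' The fraction of unmasked grid windows inside the region that pass
#' [flag_compensated_windows()] at the given threshold level for any seed
#' fraction.
#'
#' @param drt a `drt_track`
#' @param region one interval (list/row with chrom, start, end)
#' @param thresholds data.frame from [difference_thresholds()]
#' @param level threshold column, default "t_low" (the 10% threshold)
#' @param seed_fractions seed fractions considered
#' @return fraction in [0, 1]; NA for an empty/fully masked region
#' @export
compensated_fraction <- function(drt, region, thresholds, level = "t_low",
                                 seed_fractions = c("E", "L")) {
  idx <- region_window_indices(drt$grid, region$chrom, region$start,
                               region$end)
  idx <- idx[!drt$mask[idx]]
  if (!length(idx)) return(NA_real_)
  flags <- flag_compensated_windows(drt, thresholds, level, seed_fractions)
  mean(idx %in% flags$window)
}

#' Feature-level replication timing
#'
#' Mean replication signal per element, fraction and condition. Elements
#' that do not cover at least `min_overlap` bp of any single grid window are
#' excluded (default 1500 bp, half a 3-kb window); set `min_overlap = 0` to
#' keep all elements. Each included element gets the unweighted mean of the
#' unmasked windows it overlaps.
#'
#' @param elements `feature_set`
#' @param profiles named list of `replication_profile`s (e.g. mitotic,
#'   endocycle)
#' @param min_overlap minimum single-window overlap in bp
#' @return data.frame with element coordinates and one column per
#'   condition.fraction mean signal
#' @export
element_rt <- function(elements, profiles, min_overlap = 1500) {
  grid <- profiles[[1]]$grid
  ws <- grid$window_size
  keep <- vapply(seq_len(nrow(elements)), function(i) {
    idx <- region_window_indices(grid, elements$chrom[i], elements$start[i],
                                 elements$end[i])
    if (!length(idx)) return(FALSE)
    w <- grid$windows[idx, , drop = FALSE]
    ov <- pmin(w$end, elements$end[i]) - pmax(w$start, elements$start[i])
    min_overlap <= 0 || max(ov) >= min_overlap
  }, logical(1))
  kept <- elements[keep, , drop = FALSE]
  out <- data.frame(chrom = kept$chrom, start = kept$start, end = kept$end)
  for (cn in names(profiles)) {
    prof <- profiles[[cn]]
    for (f in c("E", "M", "L")) {
      out[[paste(cn, f, sep = ".")]] <-
        vapply(seq_len(nrow(kept)), function(i) {
          idx <- region_window_indices(grid, kept$chrom[i], kept$start[i],
                                       kept$end[i])
          idx <- idx[!prof$mask[idx]]
          if (!length(idx)) return(NA_real_)
          mean(prof$tracks[[f]]$values[idx])
        }, numeric(1))
    }
  }
  out
}

#' Percent AT content in grid windows
#'
#' Per window, 100 x (A+T)/(A+C+G+T); ambiguous bases are excluded from the
#' denominator and all-N windows report NA.
#'
#' @param sequences a `DNAStringSet` (names must match grid chromosomes) or
#'   path to a FASTA file
#' @param grid a `window_grid`
#' @return a `signal_track` of percent AT (all-N windows masked)
#' @export
at_content <- function(sequences, grid) {
  if (is.character(sequences))
    sequences <- Biostrings::readDNAStringSet(sequences)
  names(sequences) <- sub("\\s.*$", "", names(sequences))
  missing <- setdiff(names(grid$chromosomes), names(sequences))
  if (length(missing))
    stop("sequence missing for chromosome(s): ",
         paste(missing, collapse = ", "))
  vals <- numeric(n_windows(grid))
  mask <- logical(n_windows(grid))
  for (chr in names(grid$chromosomes)) {
    sel <- which(grid$windows$chrom == chr)
    w <- grid$windows[sel, , drop = FALSE]
    v <- Biostrings::Views(sequences[[chr]], start = w$start + 1,
                           end = w$end)
    freq <- Biostrings::letterFrequency(v, c("A", "T", "C", "G"))
    at <- freq[, "A"] + freq[, "T"]
    acgt <- rowSums(freq)
    vals[sel] <- ifelse(acgt > 0, 100 * at / acgt, 0)
    mask[sel] <- acgt == 0
  }
  signal_track(grid, vals, mask, meta = list(fraction = "wgs"))
}
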