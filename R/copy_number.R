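#' Normalized per-window read frequencies
#'
#' Counts divided by the track total and rescaled by the unmasked window
#' count, so unmasked values have mean exactly 1 and are invariant to
#' sequencing depth.
#'
#' @param track a `count_track`
#' @param mask optional logical mask
#' @return a `signal_track` with unmasked mean 1
#' @export
window_frequency <- function(track, mask = NULL) {
  if (is.null(mask)) mask <- rep(FALSE, n_windows(track$grid))
  total <- sum(track$counts[!mask])
  if (total <= 0) stop("zero total count")
  vals <- track$counts / total * sum(!mask)
  signal_track(track$grid, vals, mask, meta = track$meta)
}

#' Window copy-number ratio screen between ploidy levels
#'
#' Forms the per-window ratio of two normalized frequency tracks (numerator
#' from the higher-ploidy sample), flags windows whose ratio falls outside
#' mean +/- 2 SD, and classifies each outlier: `low_coverage` when the
#' denominator's raw count is below `min_denominator_count`, otherwise
#' `run` when an adjacent window on the same chromosome is also an outlier,
#' otherwise `singleton`. Zero-denominator windows are excluded before the
#' ratio is formed.
#'
#' @param a numerator `signal_track` (higher ploidy), from
#'   [window_frequency()]
#' @param b denominator `signal_track` (lower ploidy)
#' @param b_counts raw denominator `count_track` (for the low-coverage
#'   class); optional
#' @param min_denominator_count raw-count cutoff below which an outlier is
#'   attributed to low coverage; default: 2.5th percentile of the positive
#'   denominator counts
#' @return list of class `ratio_screen`: `ratio` (`signal_track`), `mean`,
#'   `sd`, `outliers` (data.frame window/ratio/class)
#' @export
ratio_screen <- function(a, b, b_counts = NULL,
                         min_denominator_count = NULL) {
  if (!same_grid(a$grid, b$grid)) stop("grid mismatch")
  valid <- !a$mask & !b$mask & b$values > 0
  if (!any(valid)) stop("no valid windows for the ratio")
  ratio <- rep(NA_real_, n_windows(a$grid))
  ratio[valid] <- a$values[valid] / b$values[valid]
  m <- mean(ratio[valid])
  s <- stats::sd(ratio[valid])
  out_flag <- valid & abs(ratio - m) > 2 * s
  out_flag[is.na(out_flag)] <- FALSE
  raw_b <- if (!is.null(b_counts)) b_counts$counts else b$values
  if (is.null(min_denominator_count)) {
    pos <- raw_b[valid & raw_b > 0]
    min_denominator_count <- stats::quantile(pos, 0.025, names = FALSE)
  }
  idx <- which(out_flag)
  cls <- character(length(idx))
  if (length(idx)) {
    chrom <- a$grid$windows$chrom
    neighbour <- (idx - 1) %in% idx & chrom[pmax(idx - 1, 1)] == chrom[idx] |
      (idx + 1) %in% idx &
      chrom[pmin(idx + 1, length(chrom))] == chrom[idx]
    cls <- ifelse(raw_b[idx] < min_denominator_count, "low_coverage",
                  ifelse(neighbour, "run", "singleton"))
  }
  structure(list(
    ratio = signal_track(a$grid, ifelse(is.na(ratio), 0, ratio), !valid,
                         meta = list(fraction = "wgs")),
    mean = m, sd = s, n_valid = sum(valid),
    min_denominator_count = min_denominator_count,
    outliers = data.frame(window = idx, ratio = ratio[idx], class = cls)),
    class = "ratio_screen")
}

#' @export
print.ratio_screen <- function(x, ...) {
  cat(sprintf("ratio_screen: %d windows, ratio %.3f +/- %.3f SD, %d outliers\n",
              x$n_valid, x$mean, x$sd, nrow(x$outliers)))
  invisible(x)
}

#' Summary report for copy-number screens
#'
#' One row per screen with outlier counts by class. When every outlier is a
#' singleton or attributable to low denominator coverage, the verdict states
#' there is no evidence of over- or under-replication; a screen containing
#' an outlier run withholds the verdict and lists run coordinates.
#'
#' @param screens named list of `ratio_screen` objects
#' @return data.frame with columns screen, n_windows, mean, sd,
#'   outlier_count, outlier_fraction, n_singleton, n_run, n_low_coverage,
#'   verdict
#' @export
screen_report <- function(screens) {
  if (!length(screens))
    return(data.frame(screen = character(), n_windows = integer(),
                      mean = numeric(), sd = numeric(),
                      outlier_count = integer(),
                      outlier_fraction = numeric(), n_singleton = integer(),
                      n_run = integer(), n_low_coverage = integer(),
                      verdict = character()))
  nms <- if (is.null(names(screens))) seq_along(screens) else names(screens)
  do.call(rbind, lapply(seq_along(screens), function(i) {
    sc <- screens[[i]]
    tab <- table(factor(sc$outliers$class,
                        levels = c("singleton", "run", "low_coverage")))
    verdict <- if (tab[["run"]] == 0)
      "no evidence of over/under-replication"
    else {
      runs <- sc$outliers[sc$outliers$class == "run", ]
      w <- sc$ratio$grid$windows[runs$window, , drop = FALSE]
      paste0("outlier runs at ",
             paste(unique(paste0(w$chrom, ":", w$start, "-", w$end)),
                   collapse = ", "))
    }
    data.frame(screen = nms[i], n_windows = sc$n_valid, mean = sc$mean,
               sd = sc$sd, outlier_count = nrow(sc$outliers),
               outlier_fraction = nrow(sc$outliers) / sc$n_valid,
               n_singleton = tab[["singleton"]], n_run = tab[["run"]],
               n_low_coverage = tab[["low_coverage"]], verdict = verdict)
  }))
}
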