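#' Per-window read-count track
#'
#' Non-negative integer counts, one per grid window, with sample metadata.
#'
#' @param grid a `window_grid`
#' @param counts numeric vector of non-negative counts, length `n_windows(grid)`
#' @param condition one of "mitotic", "endocycle", "none"
#' @param fraction one of "E", "M", "L", "reference", "chip", "input", "wgs"
#' @param replicate replicate index
#' @param ploidy one of "2C", "4C", "8C", "none"
#' @return an object of class `count_track`
#' @export
count_track <- function(grid, counts, condition = "none", fraction = "wgs",
                        replicate = 1L, ploidy = "none") {
  stopifnot(inherits(grid, "window_grid"))
  if (length(counts) != n_windows(grid))
    stop("counts length (", length(counts), ") != number of grid windows (",
         n_windows(grid), ")")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and >= 0")
  condition <- match.arg(condition, c("none", "mitotic", "endocycle"))
  fraction <- match.arg(fraction,
                        c("wgs", "E", "M", "L", "reference", "chip", "input"))
  ploidy <- match.arg(ploidy, c("none", "2C", "4C", "8C"))
  structure(
    list(grid = grid, counts = as.numeric(counts),
         meta = list(condition = condition, fraction = fraction,
                     replicate = as.integer(replicate), ploidy = ploidy)),
    class = "count_track"
  )
}

#' Per-window real-valued signal track with a blacklist mask
#'
#' Masked windows carry no interpretable value: every statistic in the
#' package excludes them, and any finite placeholder stored there is
#' equivalent.
#'
#' @param grid a `window_grid`
#' @param values numeric vector, length `n_windows(grid)`; must be finite on
#'   unmasked windows
#' @param mask logical vector (TRUE = blacklisted/excluded), recycled from a
#'   single FALSE if omitted
#' @param meta named list of sample metadata (condition/fraction/replicate/ploidy)
#' @return an object of class `signal_track`
#' @export
signal_track <- function(grid, values, mask = NULL, meta = list()) {
  stopifnot(inherits(grid, "window_grid"))
  n <- n_windows(grid)
  if (length(values) != n) stop("values length != number of grid windows")
  if (is.null(mask)) mask <- rep(FALSE, n)
  if (length(mask) != n) stop("mask length != number of grid windows")
  mask <- as.logical(mask)
  values <- as.numeric(values)
  if (any(!is.finite(values[!mask])))
    stop("unmasked values must be finite")
  values[mask] <- NA_real_
  structure(list(grid = grid, values = values, mask = mask, meta = meta),
            class = "signal_track")
}

#' @export
print.count_track <- function(x, ...) {
  cat(sprintf("count_track: %d windows, total %d reads [%s/%s rep %d %s]\n",
              n_windows(x$grid), round(sum(x$counts)), x$meta$condition,
              x$meta$fraction, x$meta$replicate, x$meta$ploidy))
  invisible(x)
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: %d windows (%d masked), mean %.4g\n",
              n_windows(x$grid), sum(x$mask),
              mean(x$values[!x$mask])))
  invisible(x)
}

unmasked_values <- function(track) track$values[!track$mask]
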