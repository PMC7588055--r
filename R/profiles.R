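#' Bin read/fragment intervals into grid windows
#'
#' Each fragment increments exactly one window: the window containing its
#' midpoint. A midpoint falling exactly on a window boundary belongs to the
#' right-hand window (half-open convention).
#'
#' @param read_intervals a `feature_set` of fragment spans (0-based half-open)
#' @param grid a `window_grid`
#' @param ... metadata passed to [count_track()]
#' @return a `count_track`
#' @export
bin_reads <- function(read_intervals, grid, ...) {
  mid <- (read_intervals$start + read_intervals$end) %/% 2
  idx <- window_index(grid, read_intervals$chrom, mid)
  counts <- tabulate(idx, nbins = n_windows(grid))
  count_track(grid, counts, ...)
}

#' Downsample a count track to an exact read total
#'
#' Draws `target_total` reads without replacement from the multiset of reads
#' implied by the window counts (a multivariate hypergeometric draw, realised
#' as chained univariate hypergeometrics). The output total equals
#' `target_total` exactly.
#'
#' @param track a `count_track`
#' @param target_total desired total read count (must not exceed the current
#'   total)
#' @param seed integer seed
#' @return a downsampled `count_track`
#' @export
downsample <- function(track, target_total, seed = 1L) {
  total <- sum(track$counts)
  if (target_total > total)
    stop("target_total (", target_total, ") exceeds track total (", total, ")")
  if (target_total == total) return(track)
  counts <- track$counts
  out <- numeric(length(counts))
  remaining_pool <- total
  remaining_draw <- target_total
  set.seed(seed)
  for (i in seq_along(counts)) {
    if (remaining_draw == 0) break
    ci <- counts[i]
    if (ci == 0) { remaining_pool <- remaining_pool - ci; next }
    x <- stats::rhyper(1, m = ci, n = remaining_pool - ci, k = remaining_draw)
    out[i] <- x
    remaining_draw <- remaining_draw - x
    remaining_pool <- remaining_pool - ci
  }
  tr <- track
  tr$counts <- out
  tr
}

#' Detect low-coverage blacklist windows from a 2C reference
#'
#' Natural-log-transforms the positive reference counts, fits a normal by its
#' moments, and masks windows whose ln-count falls below the distribution's
#' `low` percentile point. Zero-count windows are always masked. Windows above
#' the `high` percentile are masked only when `high < 100` (by default the
#' upper tail is kept: coverage spikes are corrected later by the reference
#' ratio instead).
#'
#' @param reference a `count_track` for the pre-replicative (2C) sample
#' @param keep_percentiles numeric `(low, high)` keep range in percent,
#'   default `c(2.5, 100)`
#' @return logical mask (TRUE = blacklisted), length `n_windows`
#' @export
detect_blacklist <- function(reference, keep_percentiles = c(2.5, 100)) {
  counts <- reference$counts
  pos <- counts > 0
  if (!any(pos)) stop("all reference counts are zero")
  if (sum(pos) < 100)
    warning("fewer than 100 positive reference windows; normal fit unstable")
  ln <- log(counts[pos])
  m <- mean(ln)
  s <- stats::sd(ln)
  mask <- !pos
  if (is.finite(s) && s > 0) {
    lo <- stats::qnorm(keep_percentiles[1] / 100, m, s)
    lnc <- rep(NA_real_, length(counts))
    lnc[pos] <- log(counts[pos])
    mask <- mask | (pos & lnc < lo)
    if (keep_percentiles[2] < 100) {
      hi <- stats::qnorm(keep_percentiles[2] / 100, m, s)
      mask <- mask | (pos & lnc > hi)
    }
  }
  mask
}

#' Scale a count track to 1x genome coverage (RPGC)
#'
#' Divides counts by the mean count over unmasked windows, so that the mean
#' unmasked value is exactly 1 (one "genome coverage" unit).
#'
#' @param track a `count_track`
#' @param mask logical blacklist mask (default: nothing masked)
#' @return a `signal_track` with mean 1 over unmasked windows
#' @export
scale_rpgc <- function(track, mask = NULL) {
  if (is.null(mask)) mask <- rep(FALSE, n_windows(track$grid))
  mu <- mean(track$counts[!mask])
  if (!is.finite(mu) || mu <= 0)
    stop("zero total count over unmasked windows")
  signal_track(track$grid, track$counts / mu, mask, meta = track$meta)
}

#' Divide a sample signal by the scaled 2C reference
#'
#' Per-window ratio on unmasked windows. Any unmasked window where the
#' reference is zero is added to the output mask (with a warning) rather
#' than producing an infinite ratio.
#'
#' @param sample,reference `signal_track`s on the same grid with the same mask
#' @return a `signal_track` of ratios
#' @export
normalize_to_reference <- function(sample, reference) {
  if (!same_grid(sample$grid, reference$grid)) stop("grid mismatch")
  if (!identical(sample$mask, reference$mask)) stop("mask mismatch")
  mask <- sample$mask
  zero_ref <- !mask & (reference$values == 0)
  if (any(zero_ref)) {
    warning(sum(zero_ref), " unmasked window(s) with zero reference signal ",
            "added to the mask")
    mask <- mask | zero_ref
  }
  vals <- rep(NA_real_, length(sample$values))
  vals[!mask] <- sample$values[!mask] / reference$values[!mask]
  signal_track(sample$grid, ifelse(mask, 0, vals), mask, meta = sample$meta)
}

# Orthonormal Haar analysis/synthesis on a power-of-two-length vector.
haar_dwt <- function(x, level) {
  details <- vector("list", level)
  for (l in seq_len(level)) {
    odd <- x[seq(1, length(x), by = 2)]
    even <- x[seq(2, length(x), by = 2)]
    details[[l]] <- (odd - even) / sqrt(2)
    x <- (odd + even) / sqrt(2)
  }
  list(approx = x, details = details)
}

haar_idwt <- function(approx, details) {
  x <- approx
  for (l in rev(seq_along(details))) {
    d <- details[[l]]
    out <- numeric(2 * length(x))
    out[seq(1, length(out), by = 2)] <- (x + d) / sqrt(2)
    out[seq(2, length(out), by = 2)] <- (x - d) / sqrt(2)
    x <- out
  }
  x
}

#' Haar wavelet smoothing of a signal track
#'
#' Per chromosome, unmasked values are bridged across masked windows by
#' linear interpolation, padded to the next power of two, Haar-transformed,
#' the `level` finest detail bands are zeroed, and the inverse transform is
#' truncated back to the chromosome length. Padding replicates the edge
#' value, which makes smoothing idempotent at a fixed level for unmasked
#' tracks of any length. The smoothed series is rescaled so the
#' per-chromosome mean over unmasked windows is preserved (multiplicatively
#' when positive, additively otherwise). Chromosomes with fewer than
#' `2^level` unmasked windows are returned unchanged with a warning.
#'
#' @param track a `signal_track`
#' @param level number of finest Haar detail bands to zero (default 3, i.e.
#'   local averaging at the 8-window / 24-kb scale on a 3-kb grid)
#' @return a smoothed `signal_track` with the same mask
#' @export
haar_smooth <- function(track, level = 3) {
  stopifnot(level >= 1)
  grid <- track$grid
  vals <- track$values
  out <- vals
  for (chr in names(grid$chromosomes)) {
    sel <- which(grid$windows$chrom == chr)
    m <- track$mask[sel]
    x <- vals[sel]
    n_un <- sum(!m)
    if (n_un == 0) next
    if (n_un < 2^level) {
      warning("chromosome ", chr, " has fewer than 2^level unmasked windows; ",
              "returned unchanged")
      next
    }
    if (any(m)) {
      idx <- seq_along(x)
      x <- stats::approx(idx[!m], x[!m], xout = idx, rule = 2)$y
    }
    n <- length(x)
    n2 <- 2^ceiling(log2(max(n, 2)))
    xp <- c(x, rep(x[n], n2 - n))
    dec <- haar_dwt(xp, level)
    for (l in seq_len(level)) dec$details[[l]][] <- 0
    sm <- haar_idwt(dec$approx, dec$details)[seq_len(n)]
    mu0 <- mean(vals[sel][!m])
    mu1 <- mean(sm[!m])
    sm <- if (mu0 > 0 && mu1 > 0) sm * (mu0 / mu1) else sm + (mu0 - mu1)
    out[sel] <- sm
  }
  out[track$mask] <- 0
  signal_track(grid, out, track$mask, meta = track$meta)
}

#' Replication profile for one condition
#'
#' Bundles the early/mid/late replication-signal tracks of one condition.
#' The three fractions share one grid and one blacklist mask.
#'
#' @param condition condition label ("mitotic" or "endocycle")
#' @param tracks named list of `signal_track`s for fractions E, M, L
#' @return an object of class `replication_profile`
#' @export
replication_profile <- function(condition, tracks) {
  stopifnot(all(c("E", "M", "L") %in% names(tracks)))
  masks <- lapply(tracks[c("E", "M", "L")], `[[`, "mask")
  if (!all(vapply(masks, identical, logical(1), y = masks[[1]])))
    stop("fraction tracks must share one mask")
  structure(list(condition = condition,
                 grid = tracks$E$grid,
                 mask = tracks$E$mask,
                 tracks = tracks[c("E", "M", "L")]),
            class = "replication_profile")
}

#' @export
print.replication_profile <- function(x, ...) {
  cat(sprintf("replication_profile [%s]: %d windows (%d masked)\n",
              x$condition, n_windows(x$grid), sum(x$mask)))
  invisible(x)
}

#' Build a replication profile from raw fraction counts
#'
#' The full normalization chain: replicates are summed per fraction; the
#' blacklist is detected from the 2C reference; reference and fractions are
#' RPGC-scaled; each fraction is divided by the scaled reference and Haar
#' smoothed. All three fraction tracks share the resulting mask.
#'
#' @param reference 2C reference `count_track`
#' @param fraction_tracks named list (`E`, `M`, `L`) of lists of replicate
#'   `count_track`s
#' @param condition condition label for the profile
#' @param level Haar smoothing level
#' @param keep_percentiles blacklist keep range, see [detect_blacklist()]
#' @return a `replication_profile`
#' @export
build_profile <- function(reference, fraction_tracks, condition = "none",
                          level = 3, keep_percentiles = c(2.5, 100)) {
  stopifnot(all(c("E", "M", "L") %in% names(fraction_tracks)))
  mask <- detect_blacklist(reference, keep_percentiles)
  ref_scaled <- scale_rpgc(reference, mask)
  smoothed <- lapply(c(E = "E", M = "M", L = "L"), function(f) {
    reps <- fraction_tracks[[f]]
    if (inherits(reps, "count_track")) reps <- list(reps)
    summed <- Reduce(`+`, lapply(reps, `[[`, "counts"))
    tr <- count_track(reference$grid, summed, condition = condition,
                      fraction = f)
    ratio <- normalize_to_reference(scale_rpgc(tr, mask), ref_scaled)
    haar_smooth(ratio, level)
  })
  # reference zeros cannot extend the mask here (zero-count windows are
  # already blacklisted), so the three fractions share the blacklist mask
  replication_profile(condition, smoothed)
}

#' Pairwise Pearson correlation between replicate tracks
#'
#' Correlations are computed over windows unmasked in every track. Pairs in
#' which either track has zero variance are reported as NA.
#'
#' @param tracks list of >= 2 `signal_track`s or `count_track`s on one grid
#' @return symmetric matrix of Pearson r
#' @export
replicate_correlation <- function(tracks) {
  stopifnot(length(tracks) >= 2)
  vals <- lapply(tracks, function(t)
    if (inherits(t, "count_track")) t$counts else t$values)
  masks <- lapply(tracks, function(t)
    if (inherits(t, "count_track")) rep(FALSE, length(t$counts)) else t$mask)
  keep <- !Reduce(`|`, masks)
  k <- length(tracks)
  r <- matrix(NA_real_, k, k)
  diag(r) <- 1
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    xi <- vals[[i]][keep]; xj <- vals[[j]][keep]
    if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next
    r[i, j] <- r[j, i] <- stats::cor(xi, xj)
  }
  r
}
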