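# Shared fixtures built in code.

toy_grid <- function(lengths = c(chr1 = 60000, chr2 = 60000),
                     window_size = 3000) {
  window_grid(lengths, window_size)
}

# A replication profile built directly from per-fraction values (no masks
# unless given); bypasses the normalization chain for unit tests of the
# RAT caller.
toy_profile <- function(grid, E, M, L, mask = NULL, condition = "none") {
  replication_profile(condition, list(
    E = signal_track(grid, E, mask, meta = list(fraction = "E")),
    M = signal_track(grid, M, mask, meta = list(fraction = "M")),
    L = signal_track(grid, L, mask, meta = list(fraction = "L"))))
}

# Profiles from timing matrices: signal_f = 3 * p_f (each fraction's
# genome-wide mean is 1/3 on the simplex), noise-free.
profile_from_timing <- function(grid, timing, condition = "none") {
  toy_profile(grid, 3 * timing[, 1], 3 * timing[, 2], 3 * timing[, 3],
              condition = condition)
}

# Memoised default synthetic study + profiles + calls (used by several
# heavier tests so the ~20 s end-to-end chain runs once per suite).
study_cache <- new.env(parent = emptyenv())
default_study_run <- function(seed = 7) {
  key <- paste0("s", seed)
  if (!is.null(study_cache[[key]])) return(study_cache[[key]])
  cfg <- pipeline_config(seed = seed)
  st <- suppressWarnings(simulate_study(cfg))
  prof_m <- build_profile(st$reference, st$mitotic, "mitotic",
                          level = cfg$wavelet_level)
  prof_e <- build_profile(st$reference, st$endocycle, "endocycle",
                          level = cfg$wavelet_level)
  cen <- st$features[st$features$kind == "CEN", ]
  calls <- call_rats(prof_e, prof_m, cen = cen, config = cfg)
  res <- list(cfg = cfg, study = st, mito = prof_m, endo = prof_e,
              cen = cen, calls = calls)
  study_cache[[key]] <- res
  res
}

# Independent brute-force interval merge with a gap allowance: repeatedly
# join any pair of intervals on the same chromosome whose gap is <= gap bp.
brute_merge <- function(df, gap) {
  rows <- split(df, seq_len(nrow(df)))
  changed <- TRUE
  while (changed && length(rows) > 1) {
    changed <- FALSE
    for (i in seq_along(rows)) {
      for (j in seq_along(rows)) {
        if (i >= j) next
        a <- rows[[i]]; b <- rows[[j]]
        if (a$chrom != b$chrom) next
        if (max(a$start, b$start) - min(a$end, b$end) <= gap) {
          rows[[i]]$start <- min(a$start, b$start)
          rows[[i]]$end <- max(a$end, b$end)
          rows[[j]] <- NULL
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start), c("chrom", "start", "end")]
}
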