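#' Per-window differences in replication timing (DRT)
#'
#' Signed per-window difference (endocycle minus mitotic) of the
#' replication signal, per S-phase fraction.
#'
#' @param endo,mito `replication_profile`s on the same grid with the same mask
#' @return an object of class `drt_track` with elements `grid`, `mask`, and
#'   `diffs` (named list of numeric vectors for E, M, L)
#' @export
compute_drt <- function(endo, mito) {
  if (!same_grid(endo$grid, mito$grid)) stop("grid mismatch")
  if (!identical(endo$mask, mito$mask)) stop("mask mismatch")
  diffs <- lapply(c(E = "E", M = "M", L = "L"), function(f) {
    d <- endo$tracks[[f]]$values - mito$tracks[[f]]$values
    d[endo$mask] <- NA_real_
    d
  })
  structure(list(grid = endo$grid, mask = endo$mask, diffs = diffs),
            class = "drt_track")
}

#' DRT thresholds from per-chromosome difference extremes
#'
#' For each fraction, the maximum positive and maximum negative (signed
#' minimum) differences are taken per chromosome and averaged across
#' chromosomes. The total range is their difference, and the calling
#' thresholds are fixed percentages of that range (defaults 10% and 25%).
#' A zero range yields infinite thresholds (no window can seed) with a
#' warning.
#'
#' @param drt a `drt_track`
#' @param threshold_low,threshold_high threshold percentages of the range
#' @return data.frame with one row per fraction: `avg_max_pos`,
#'   `avg_max_neg`, `range`, `t_low`, `t_high`
#' @export
difference_thresholds <- function(drt, threshold_low = 10,
                                  threshold_high = 25) {
  chrom <- drt$grid$windows$chrom
  rows <- lapply(c("E", "M", "L"), function(f) {
    d <- drt$diffs[[f]]
    per_chr <- lapply(split(d[!drt$mask], chrom[!drt$mask]), function(x) {
      if (!length(x)) c(NA_real_, NA_real_) else c(max(x), min(x))
    })
    per_chr <- do.call(rbind, per_chr)
    amp <- mean(per_chr[, 1], na.rm = TRUE)
    amn <- mean(per_chr[, 2], na.rm = TRUE)
    rng <- amp - amn
    data.frame(fraction = f, avg_max_pos = amp, avg_max_neg = amn,
               range = rng,
               t_low = if (rng > 0) threshold_low / 100 * rng else Inf,
               t_high = if (rng > 0) threshold_high / 100 * rng else Inf)
  })
  out <- do.call(rbind, rows)
  if (any(!is.finite(out$t_low)))
    warning("zero difference range in fraction(s) ",
            paste(out$fraction[!is.finite(out$t_low)], collapse = ", "),
            ": no window can seed")
  out
}

#' Flag windows with compensated timing differences
#'
#' A window is flagged for seed fraction f when its difference magnitude
#' reaches the threshold, |d_f| >= t, and the summed opposite-sign
#' difference magnitude over the other two fractions also reaches it:
#' sum_g max(0, -sign(d_f) * d_g) >= t. This is the compensation rule: a
#' loss of replication signal in one fraction must be matched by an equal
#' or greater gain in the other fraction(s) of the same cell population.
#'
#' @param drt a `drt_track`
#' @param thresholds data.frame from [difference_thresholds()]
#' @param level which threshold column to apply: "t_low" (10%) or "t_high"
#'   (25%)
#' @param seed_fractions fractions allowed to seed (default early and late;
#'   mid contributes through compensation only)
#' @return data.frame of flags with columns `window` (grid index),
#'   `fraction`, `sign`
#' @export
flag_compensated_windows <- function(drt, thresholds,
                                     level = c("t_high", "t_low"),
                                     seed_fractions = c("E", "L")) {
  level <- match.arg(level)
  fractions <- c("E", "M", "L")
  out <- list()
  for (f in seed_fractions) {
    t <- thresholds[[level]][thresholds$fraction == f]
    if (!is.finite(t)) next
    d <- drt$diffs[[f]]
    others <- setdiff(fractions, f)
    s <- sign(d)
    comp <- rowSums(vapply(others, function(g)
      pmax(0, -s * drt$diffs[[g]]), numeric(length(d))))
    hit <- !drt$mask & abs(d) >= t & comp >= t
    hit[is.na(hit)] <- FALSE
    if (any(hit))
      out[[f]] <- data.frame(window = which(hit), fraction = f,
                             sign = s[hit])
  }
  if (!length(out))
    return(data.frame(window = integer(), fraction = character(),
                      sign = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$window), , drop = FALSE]
}

#' Merge flagged windows into intervals with a gap allowance
#'
#' Flagged windows whose inter-window distance is at most `gap` bp are
#' merged into maximal intervals (bedtools merge -d semantics). The gap
#' allowance absorbs small blacklist interruptions.
#'
#' @param windows integer grid indices of flagged windows (any fraction)
#' @param grid the `window_grid`
#' @param gap merge gap distance in bp (default 6000)
#' @return a `feature_set` of merged intervals
#' @export
merge_flagged <- function(windows, grid, gap = 6000) {
  windows <- sort(unique(windows))
  if (!length(windows))
    return(feature_set(kind = character()))
  w <- grid$windows[windows, , drop = FALSE]
  gr <- GenomicRanges::GRanges(w$chrom,
                               IRanges::IRanges(w$start + 1, w$end))
  merged <- GenomicRanges::reduce(gr, min.gapwidth = gap + 1)
  granges_features(merged, kind = "RAT")
}

#' Assemble robust RATs from the two threshold levels
#'
#' Low-threshold (>= 10%) regions overlapping or lying within the gap
#' distance of a high-threshold (>= 25%) core are merged with it; regions
#' with no core are discarded. Every reported RAT therefore contains at
#' least one >= 25% core window, which filters out stand-alone tiny regions
#' without an arbitrary size cutoff.
#'
#' @param regions_low `feature_set` of merged >= 10% regions
#' @param regions_high `feature_set` of merged >= 25% regions
#' @param gap merge gap distance in bp
#' @return a `feature_set` of RAT intervals with column `has_core25`
#' @export
build_rats <- function(regions_low, regions_high, gap = 6000) {
  if (nrow(regions_high) == 0)
    return(feature_set(kind = character()))
  al <- align_seqlevels(features_granges(regions_low),
                        features_granges(regions_high))
  merged <- GenomicRanges::reduce(c(al$a, al$b), min.gapwidth = gap + 1)
  keep <- IRanges::overlapsAny(merged, al$b)
  out <- granges_features(merged[keep], kind = "RAT")
  out$has_core25 <- TRUE
  out
}

#' Classify the direction of a timing shift
#'
#' Computes S, the sum over the region's unmasked windows of the late minus
#' early DRT. Positive S means replication signal moved into late S in the
#' endocycle (Earlier-to-Later); negative S means the reverse. An exact tie
#' is broken by the sign of the summed mid DRT.
#'
#' @param region one interval (list/row with chrom, start, end)
#' @param drt a `drt_track`
#' @return "Earlier-to-Later" or "Later-to-Earlier"
#' @export
classify_direction <- function(region, drt) {
  idx <- region_window_indices(drt$grid, region$chrom, region$start,
                               region$end)
  idx <- idx[!drt$mask[idx]]
  if (!length(idx)) return(NA_character_)
  s <- sum(drt$diffs$L[idx] - drt$diffs$E[idx])
  if (s > 0) return("Earlier-to-Later")
  if (s < 0) return("Later-to-Earlier")
  if (sum(drt$diffs$M[idx]) > 0) "Earlier-to-Later" else "Later-to-Earlier"
}

# Grid indices of windows overlapping [start, end) on chrom (>= 1 bp).
region_window_indices <- function(grid, chrom, start, end) {
  if (!chrom %in% names(grid$chromosomes)) return(integer())
  ws <- grid$window_size
  clen <- grid$chromosomes[[chrom]]
  lo <- max(0, start) %/% ws
  hi <- (min(end, clen) - 1) %/% ws
  if (hi < lo) return(integer())
  as.integer(grid$offsets[[chrom]] + lo:hi + 1)
}

#' Mark centromeric RATs
#'
#' Earlier-to-Later RATs overlapping a functional centromere by at least one
#' bp become category "Earlier-to-Later-CEN"; the portion of such a RAT
#' lying outside the CEN boundary is recorded as presumed-CEN coverage.
#' Later-to-Earlier RATs are never reclassified (no such centromeric
#' category exists).
#'
#' @param rats `feature_set` of RATs with a `category` column
#' @param cen `feature_set` of centromere intervals
#' @return `rats` with updated `category` and new `presumed_cen_bp` column
#' @export
annotate_cen <- function(rats, cen) {
  rats$presumed_cen_bp <- 0
  if (nrow(rats) == 0 || nrow(cen) == 0) return(rats)
  al <- align_seqlevels(features_granges(rats),
                        GenomicRanges::reduce(features_granges(cen)))
  rat_gr <- al$a
  cen_gr <- al$b
  ov <- IRanges::overlapsAny(rat_gr, cen_gr)
  hit <- ov & rats$category == "Earlier-to-Later"
  if (any(hit)) {
    rats$category[hit] <- "Earlier-to-Later-CEN"
    inside_bp <- vapply(seq_len(sum(hit)), function(i) {
      sum(IRanges::width(GenomicRanges::intersect(rat_gr[hit][i], cen_gr)))
    }, numeric(1))
    rats$presumed_cen_bp[hit] <-
      (rats$end[hit] - rats$start[hit]) - inside_bp
  }
  rats
}

#' Continuous RAT size estimate for one centromere
#'
#' Automated calling breaks centromeric RATs on blacklist windows. This
#' reconstructs an upper size estimate by merging the CEN RATs (including
#' their presumed portions outside the CEN boundary) with the blacklist
#' intervals interspersed between them, trimming each merged run to the
#' outermost RAT boundaries. Also reports the fraction of the CEN covered by
#' the continuous RAT, ignoring presumed portions outside the boundary.
#'
#' @param rats_in_cen `feature_set` of RATs assigned to this centromere
#' @param blacklist `feature_set` of blacklist intervals
#' @param cen one centromere interval (list/row with chrom, start, end)
#' @return one-row data.frame: `cen_size_bp`, `cen_excl_blacklist_bp`,
#'   `rat_coverage_bp`, `presumed_cen_bp`, `rat_count`, `continuous_bp`,
#'   `pct_cen_covered` (NA when the centromere holds no RAT)
#' @export
continuous_cen_size <- function(rats_in_cen, blacklist, cen) {
  cen_gr <- GenomicRanges::GRanges(cen$chrom,
                                   IRanges::IRanges(cen$start + 1, cen$end))
  cen_size <- cen$end - cen$start
  bl_gr <- if (nrow(blacklist)) features_granges(blacklist)
  else GenomicRanges::GRanges()
  al0 <- align_seqlevels(cen_gr, bl_gr)
  cen_gr <- al0$a; bl_gr <- al0$b
  bl_in_cen <- sum(IRanges::width(GenomicRanges::intersect(
    GenomicRanges::reduce(bl_gr), cen_gr)))
  base <- data.frame(cen_size_bp = cen_size,
                     cen_excl_blacklist_bp = cen_size - bl_in_cen,
                     rat_coverage_bp = NA_real_, presumed_cen_bp = NA_real_,
                     rat_count = nrow(rats_in_cen),
                     continuous_bp = NA_real_, pct_cen_covered = NA_real_)
  if (nrow(rats_in_cen) == 0) return(base)
  al1 <- align_seqlevels(
    GenomicRanges::reduce(features_granges(rats_in_cen)), cen_gr)
  rat_gr <- al1$a; cen_gr <- al1$b
  GenomeInfoDb::seqlevels(bl_gr) <- GenomeInfoDb::seqlevels(cen_gr)
  base$rat_coverage_bp <- sum(IRanges::width(
    GenomicRanges::intersect(rat_gr, cen_gr)))
  base$presumed_cen_bp <- sum(IRanges::width(rat_gr)) - base$rat_coverage_bp
  comp <- GenomicRanges::reduce(c(rat_gr, bl_gr), min.gapwidth = 1)
  has_rat <- IRanges::overlapsAny(comp, rat_gr)
  spans <- lapply(which(has_rat), function(i) {
    inside <- rat_gr[IRanges::overlapsAny(rat_gr, comp[i])]
    GenomicRanges::GRanges(
      GenomeInfoDb::seqnames(comp[i]),
      IRanges::IRanges(min(GenomicRanges::start(inside)),
                       max(GenomicRanges::end(inside))))
  })
  spans <- GenomicRanges::reduce(do.call(c, spans))
  base$continuous_bp <- sum(IRanges::width(spans))
  base$pct_cen_covered <- 100 * sum(IRanges::width(
    GenomicRanges::intersect(spans, cen_gr))) / cen_size
  base
}

#' Summary table of called RATs
#'
#' Per direction category and in total: region count, median size (kb),
#' summed coverage (kb) and coverage as a percentage of the genome.
#'
#' @param rats `feature_set` of RATs with a `category` column
#' @param genome_size total genome size in bp
#' @return data.frame with columns `category`, `count`, `median_size_kb`,
#'   `coverage_kb`, `pct_genome`
#' @export
summarize_rats <- function(rats, genome_size) {
  cats <- c("Later-to-Earlier", "Earlier-to-Later", "Earlier-to-Later-CEN")
  sizes <- rats$end - rats$start
  rows <- lapply(cats, function(cc) {
    s <- sizes[rats$category == cc]
    data.frame(category = cc, count = length(s),
               median_size_kb = if (length(s)) stats::median(s) / 1000
               else NA_real_,
               coverage_kb = if (length(s)) sum(s) / 1000 else NA_real_,
               pct_genome = if (length(s)) 100 * sum(s) / genome_size
               else NA_real_)
  })
  tot <- data.frame(category = "Total", count = length(sizes),
                    median_size_kb = if (length(sizes))
                      stats::median(sizes) / 1000 else NA_real_,
                    coverage_kb = sum(sizes) / 1000,
                    pct_genome = 100 * sum(sizes) / genome_size)
  rbind(do.call(rbind, rows), tot)
}

#' Call Regions of Altered Timing between two conditions
#'
#' The full calling chain: per-fraction DRT, per-chromosome threshold
#' derivation, compensated-window flagging at both threshold levels, gap
#' merging of each level, assembly of robust RATs around >= 25% cores,
#' direction classification, and (when centromere coordinates are supplied)
#' centromeric annotation.
#'
#' @param endo,mito `replication_profile`s (endocycle and mitotic)
#' @param cen optional `feature_set` of centromere intervals
#' @param config a [pipeline_config()]
#' @return list with `rats` (a `feature_set` with `category`, `size_bp`,
#'   per-fraction mean DRT columns), `drt`, `thresholds`, `flags_low`,
#'   `flags_high`, `regions_low`, `regions_high`
#' @export
call_rats <- function(endo, mito, cen = NULL, config = pipeline_config()) {
  drt <- compute_drt(endo, mito)
  thr <- difference_thresholds(drt, config$threshold_low,
                               config$threshold_high)
  fl_low <- flag_compensated_windows(drt, thr, "t_low",
                                     config$seed_fractions)
  fl_high <- flag_compensated_windows(drt, thr, "t_high",
                                      config$seed_fractions)
  reg_low <- merge_flagged(fl_low$window, drt$grid, config$gap_bp)
  reg_high <- merge_flagged(fl_high$window, drt$grid, config$gap_bp)
  rats <- build_rats(reg_low, reg_high, config$gap_bp)
  if (nrow(rats)) {
    rats$size_bp <- rats$end - rats$start
    rats$category <- vapply(seq_len(nrow(rats)), function(i)
      classify_direction(rats[i, ], drt), character(1))
    for (f in c("E", "M", "L"))
      rats[[paste0("mean_drt_", f)]] <-
        vapply(seq_len(nrow(rats)), function(i) {
          idx <- region_window_indices(drt$grid, rats$chrom[i],
                                       rats$start[i], rats$end[i])
          mean(drt$diffs[[f]][idx], na.rm = TRUE)
        }, numeric(1))
  } else {
    rats$size_bp <- numeric(0)
    rats$category <- character(0)
  }
  if (!is.null(cen) && nrow(rats)) rats <- annotate_cen(rats, cen)
  list(rats = rats, drt = drt, thresholds = thr,
       flags_low = fl_low, flags_high = fl_high,
       regions_low = reg_low, regions_high = reg_high)
}
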