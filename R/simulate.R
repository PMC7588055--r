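#' Generate a synthetic genome with annotations
#'
#' Builds a window grid plus a feature set containing one centromere per
#' chromosome (centered), its pericentromeric flanks, random gene islands
#' (with expressed flags), TE blocks, and window-aligned blacklist intervals
#' covering a configurable fraction of the genome.
#'
#' @param n_chrom number of chromosomes
#' @param chrom_length chromosome length in bp (all chromosomes equal)
#' @param window_size grid window size in bp
#' @param seed integer seed
#' @param cen_size centromere size in bp
#' @param pericen_flank_bp pericentromere flank in bp
#' @param blacklist_fraction approximate fraction of windows blacklisted
#' @param n_genes,n_tes feature counts per chromosome
#' @return list with `grid` (a `window_grid`) and `features` (a
#'   `feature_set` with kinds gene, TE, CEN, pericentromere, blacklist)
#' @export
make_genome <- function(n_chrom = 2, chrom_length = 30e6, window_size = 3000,
                        seed = 1L, cen_size = 2e6, pericen_flank_bp = 1e6,
                        blacklist_fraction = 0.04, n_genes = 400,
                        n_tes = 200) {
  stopifnot(chrom_length >= 10 * window_size)
  chroms <- stats::setNames(rep(chrom_length, n_chrom),
                            paste0("chr", seq_len(n_chrom)))
  grid <- window_grid(chroms, window_size)
  set.seed(seed)
  feats <- list()
  for (chr in names(chroms)) {
    len <- chroms[[chr]]
    cs <- round(len / 2 - cen_size / 2)
    ce <- cs + cen_size
    if (cs - pericen_flank_bp < 0 || ce + pericen_flank_bp > len)
      stop("pericentromere flank larger than chromosome arm")
    feats[[length(feats) + 1]] <- feature_set(
      chrom = rep(chr, 3), start = c(cs, cs - pericen_flank_bp, ce),
      end = c(ce, cs, ce + pericen_flank_bp),
      kind = c("CEN", "pericentromere", "pericentromere"))
    gs <- sort(sample.int(len - 20000, n_genes))
    feats[[length(feats) + 1]] <- feature_set(
      chrom = rep(chr, n_genes), start = gs,
      end = gs + sample(1000:8000, n_genes, replace = TRUE),
      kind = "gene", expressed = stats::runif(n_genes) < 0.7)
    ts <- sort(sample.int(len - 30000, n_tes))
    feats[[length(feats) + 1]] <- feature_set(
      chrom = rep(chr, n_tes), start = ts,
      end = ts + sample(2000:15000, n_tes, replace = TRUE),
      kind = "TE",
      superfamily = sample(c("RLG", "RLC", "DTA"), n_tes, replace = TRUE))
    # window-aligned blacklist runs of 1-3 windows
    nw <- len %/% window_size
    n_bl <- max(1, round(blacklist_fraction * nw / 2))
    bs <- sort(sample.int(nw - 3, n_bl)) - 1
    bw <- sample(1:3, n_bl, replace = TRUE)
    feats[[length(feats) + 1]] <- feature_set(
      chrom = rep(chr, n_bl), start = bs * window_size,
      end = (bs + bw) * window_size, kind = "blacklist")
  }
  features <- bind_features(feats)
  list(grid = grid, features = features)
}

#' Default injected-RAT specification for the synthetic genome
#'
#' Places compensated timing shifts of 30-150 kb on both chromosome arms,
#' clear of the pericentromeric region, with alternating directions and a
#' 0.6 timing-mass shift.
#'
#' @param grid a `window_grid`
#' @param magnitude timing-mass shift per injected region
#' @return data.frame with columns chrom, start, end, direction, magnitude
#' @export
default_rat_spec <- function(grid, magnitude = 0.6) {
  sizes <- c(30e3, 60e3, 90e3, 120e3, 150e3, 60e3, 90e3, 120e3)
  starts <- c(2e6, 5e6, 8e6, 11e6, 18e6, 21e6, 24e6, 27e6)
  dirs <- rep(c("Earlier-to-Later", "Later-to-Earlier"), 4)
  out <- do.call(rbind, lapply(names(grid$chromosomes), function(chr) {
    keep <- starts + sizes <= grid$chromosomes[[chr]]
    data.frame(chrom = chr, start = starts[keep],
               end = starts[keep] + sizes[keep], direction = dirs[keep],
               magnitude = magnitude)
  }))
  out
}

smooth_field <- function(n, bw, seed_vec) {
  x <- seed_vec
  k <- rep(1 / bw, bw)
  y <- stats::filter(x, k, sides = 2)
  y[is.na(y)] <- mean(x)
  as.numeric(y)
}

#' Simulate replication-timing mixtures for two conditions
#'
#' Baseline timing is a spatially autocorrelated random field mapped to the
#' 3-simplex (per-window probabilities that replication occurs in early, mid
#' or late S). The endocycle model equals the mitotic model except inside
#' injected regions, where `magnitude` of probability mass is moved between
#' fractions in the stated direction (Earlier-to-Later: early to late;
#' Later-to-Earlier: late to early), and inside centromeres, which receive a
#' mid-to-late template shift. Mass is moved, never created: rows always sum
#' to one, and shifts exceeding the available mass are clipped (recorded in
#' the truth object).
#'
#' @param grid a `window_grid`
#' @param features `feature_set` from [make_genome()] (CEN intervals used)
#' @param rat_spec data.frame(chrom, start, end, direction, magnitude) of
#'   injected shifts; intervals must not overlap
#' @param seed integer seed
#' @param cen_shift mid-to-late mass shift inside centromeres (0 disables)
#' @param autocorr_bw smoothing bandwidth (windows) of the baseline field
#' @return list with `mitotic` and `endocycle` (n x 3 matrices of pE, pM,
#'   pL) and `truth` (injected intervals with directions, blacklist,
#'   clipping flags)
#' @export
simulate_timing <- function(grid, features, rat_spec = NULL, seed = 1L,
                            cen_shift = 0.5, autocorr_bw = 41) {
  n <- n_windows(grid)
  set.seed(stage_seed(seed, "timing"))
  z <- matrix(0, n, 3)
  for (chr in names(grid$chromosomes)) {
    sel <- which(grid$windows$chrom == chr)
    for (j in 1:3)
      z[sel, j] <- smooth_field(length(sel), autocorr_bw,
                                stats::rnorm(length(sel)))
  }
  z <- z * sqrt(autocorr_bw) * 1.2   # restore unit-ish scale after averaging
  # regions destined to shift replicate predominantly in the source
  # fraction to begin with (cf. centromeres replicating mainly in mid S),
  # so the injected mass transfer is feasible without clipping
  fcol <- c(pE = 1, pM = 2, pL = 3)
  if (!is.null(rat_spec) && nrow(rat_spec)) {
    for (i in seq_len(nrow(rat_spec))) {
      idx <- region_window_indices(grid, rat_spec$chrom[i],
                                   rat_spec$start[i], rat_spec$end[i])
      src <- if (rat_spec$direction[i] == "Earlier-to-Later") "pE" else "pL"
      z[idx, fcol[[src]]] <- z[idx, fcol[[src]]] + 2.5
    }
  }
  cen_bias <- subset_features(features, "CEN")
  if (cen_shift > 0 && nrow(cen_bias)) {
    for (i in seq_len(nrow(cen_bias))) {
      idx <- region_window_indices(grid, cen_bias$chrom[i],
                                   cen_bias$start[i], cen_bias$end[i])
      z[idx, fcol[["pM"]]] <- z[idx, fcol[["pM"]]] + 2.5
    }
  }
  p <- exp(z)
  p <- p / rowSums(p)
  mito <- endo <- p
  colnames(mito) <- colnames(endo) <- c("pE", "pM", "pL")
  if (!is.null(rat_spec) && nrow(rat_spec)) {
    gr <- features_granges(rat_spec)
    if (sum(IRanges::width(GenomicRanges::reduce(gr))) !=
        sum(IRanges::width(gr)))
      stop("rat_spec intervals must not overlap")
  }
  clipped <- logical(0)
  truth_rows <- list()
  apply_shift <- function(mat, idx, from, to, mag) {
    avail <- mat[idx, from]
    move <- pmin(mag, avail)
    mat[idx, from] <- mat[idx, from] - move
    mat[idx, to] <- mat[idx, to] + move
    list(mat = mat, clipped = any(move < mag - 1e-12))
  }
  if (!is.null(rat_spec)) {
    for (i in seq_len(nrow(rat_spec))) {
      idx <- region_window_indices(grid, rat_spec$chrom[i],
                                   rat_spec$start[i], rat_spec$end[i])
      ft <- if (rat_spec$direction[i] == "Earlier-to-Later") c("pE", "pL")
      else c("pL", "pE")
      res <- apply_shift(endo, idx, ft[1], ft[2], rat_spec$magnitude[i])
      endo <- res$mat
      if (res$clipped)
        warning("shift clipped in injected region ", i,
                " (insufficient source mass)")
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        chrom = rat_spec$chrom[i], start = rat_spec$start[i],
        end = rat_spec$end[i], direction = rat_spec$direction[i],
        magnitude = rat_spec$magnitude[i], cen = FALSE,
        clipped = res$clipped)
    }
  }
  cen <- subset_features(features, "CEN")
  if (cen_shift > 0 && nrow(cen)) {
    for (i in seq_len(nrow(cen))) {
      idx <- region_window_indices(grid, cen$chrom[i], cen$start[i],
                                   cen$end[i])
      res <- apply_shift(endo, idx, "pM", "pL", cen_shift)
      endo <- res$mat
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        chrom = cen$chrom[i], start = cen$start[i], end = cen$end[i],
        direction = "Earlier-to-Later", magnitude = cen_shift, cen = TRUE,
        clipped = res$clipped)
    }
  }
  truth <- list(
    rats = if (length(truth_rows)) do.call(rbind, truth_rows)
    else data.frame(chrom = character(), start = numeric(),
                    end = numeric(), direction = character(),
                    magnitude = numeric(), cen = logical(),
                    clipped = logical()),
    blacklist = subset_features(features, "blacklist"))
  list(mitotic = mito, endocycle = endo, truth = truth)
}

#' Per-window mappability multipliers
#'
#' Lognormal multipliers emulate mappability variation and collapsed-repeat
#' coverage spikes; blacklist windows get near-zero mappability so they fall
#' into the lower tail of the 2C reference count distribution.
#'
#' @param grid a `window_grid`
#' @param blacklist_mask logical vector (TRUE = blacklisted window)
#' @param seed integer seed
#' @param sdlog lognormal sd of the multipliers
#' @return numeric vector of multipliers
#' @export
make_mappability <- function(grid, blacklist_mask = NULL, seed = 1L,
                             sdlog = 0.25) {
  set.seed(stage_seed(seed, "mappability"))
  m <- stats::rlnorm(n_windows(grid), meanlog = 0, sdlog = sdlog)
  if (!is.null(blacklist_mask)) m[blacklist_mask] <- m[blacklist_mask] * 0.02
  m
}

#' Simulate fraction-resolved Repli-seq counts
#'
#' Expected fraction-f counts per window are proportional to
#' mappability x p_f; the 2C reference is proportional to mappability only.
#' Counts are negative binomial with the given dispersion (Poisson in the
#' dispersion -> 0 limit).
#'
#' @param timing n x 3 timing matrix (columns pE, pM, pL)
#' @param grid a `window_grid`
#' @param mappability per-window multipliers from [make_mappability()]
#' @param depth expected total reads per fraction sample
#' @param dispersion negative-binomial dispersion (variance = mu + disp*mu^2)
#' @param n_replicates replicates per fraction
#' @param seed integer seed
#' @param condition condition label stored in track metadata
#' @return list with `fractions` (named list E/M/L of replicate
#'   `count_track` lists) and `reference` (2C `count_track`)
#' @export
simulate_repliseq <- function(timing, grid, mappability, depth = 2e6,
                              dispersion = 0.05, n_replicates = 3,
                              seed = 1L, condition = "none") {
  stopifnot(depth > 0)
  set.seed(stage_seed(seed, paste0("repliseq-", condition)))
  draw <- function(lambda) {
    if (dispersion <= 0) stats::rpois(length(lambda), lambda)
    else stats::rnbinom(length(lambda), mu = lambda, size = 1 / dispersion)
  }
  fractions <- lapply(c(E = 1, M = 2, L = 3), function(j) {
    w <- mappability * timing[, j]
    lambda <- depth * w / sum(w)
    lapply(seq_len(n_replicates), function(r)
      count_track(grid, draw(lambda), condition = condition,
                  fraction = c("E", "M", "L")[j], replicate = r))
  })
  lam_ref <- depth * mappability / sum(mappability)
  reference <- count_track(grid, draw(lam_ref), condition = condition,
                           fraction = "reference", ploidy = "2C")
  list(fractions = fractions, reference = reference)
}

#' Simulate a WGS ploidy pair for copy-number screening
#'
#' Both tracks share uniform expected per-window rates except inside CNV
#' intervals, where track B's rate is multiplied by the true ratio.
#'
#' @param grid a `window_grid`
#' @param cnv_spec optional data.frame(chrom, start, end, ratio)
#' @param depth expected total reads per track
#' @param seed integer seed
#' @return list with `a`, `b` (`count_track`s, A is the lower-ploidy
#'   denominator) and `truth` (the CNV spec)
#' @export
simulate_wgs <- function(grid, cnv_spec = NULL, depth = 5e6, seed = 1L) {
  n <- n_windows(grid)
  set.seed(stage_seed(seed, "wgs"))
  rate_a <- rep(depth / n, n)
  rate_b <- rate_a
  if (!is.null(cnv_spec) && nrow(cnv_spec)) {
    for (i in seq_len(nrow(cnv_spec))) {
      idx <- region_window_indices(grid, cnv_spec$chrom[i],
                                   cnv_spec$start[i], cnv_spec$end[i])
      rate_b[idx] <- rate_b[idx] * cnv_spec$ratio[i]
    }
  }
  a <- count_track(grid, stats::rpois(n, rate_a), fraction = "wgs",
                   ploidy = "2C")
  b <- count_track(grid, stats::rpois(n, rate_b), fraction = "wgs",
                   ploidy = "4C")
  list(a = a, b = b, truth = cnv_spec)
}

#' Simulate ChIP and input tracks across ploidy levels
#'
#' The input read share of the target region equals its DNA share; the ChIP
#' read share is `enrichment` times that for 2C nuclei, scaled by the
#' redeposition-model factor (1 + f)/2 per replication round for 4C (round
#' 1) and 8C (rounds 1 and 2). The expected [region_enrichment()] statistic
#' therefore equals `enrichment` times the cumulative model factor.
#'
#' @param grid a `window_grid`
#' @param region one interval (list/row with chrom, start, end)
#' @param enrichment fold enrichment of ChIP read share over DNA share at 2C
#' @param f_redeposition length-2 vector: redeposited deficit fraction for
#'   round 1 (2C to 4C) and round 2 (4C to 8C)
#' @param depth expected reads per track
#' @param n_replicates ChIP replicates per ploidy
#' @param seed integer seed
#' @return list with per-ploidy `chip` replicate lists and `input` tracks,
#'   plus `truth` (expected region enrichment per ploidy)
#' @export
simulate_chip <- function(grid, region, enrichment = 20,
                          f_redeposition = c(1, 0.4), depth = 1e6,
                          n_replicates = 3, seed = 1L) {
  stopifnot(all(f_redeposition >= 0 & f_redeposition <= 1))
  n <- n_windows(grid)
  idx <- region_window_indices(grid, region$chrom, region$start, region$end)
  nr <- length(idx)
  set.seed(stage_seed(seed, "chip"))
  factors <- c(`2C` = 1,
               `4C` = (1 + f_redeposition[1]) / 2,
               `8C` = (1 + f_redeposition[1]) / 2 *
                 (1 + f_redeposition[2]) / 2)
  out <- list(chip = list(), input = list(),
              truth = list(region = region,
                           expected_enrichment = enrichment * factors,
                           f_redeposition = f_redeposition))
  for (pl in names(factors)) {
    target_share <- min(enrichment * factors[[pl]] * nr / n, 0.99)
    p <- rep((1 - target_share) / (n - nr), n)
    p[idx] <- target_share / nr
    out$chip[[pl]] <- lapply(seq_len(n_replicates), function(r)
      count_track(grid, stats::rpois(n, depth * p), fraction = "chip",
                  replicate = r, ploidy = pl))
    out$input[[pl]] <- count_track(grid, stats::rpois(n, depth / n),
                                   fraction = "input", ploidy = pl)
  }
  out
}

#' Recall and precision of called RATs against simulation truth
#'
#' A truth region is recovered when at least `min_fraction` of its length is
#' covered by called RATs of the same direction; a called RAT is correct
#' when at least `min_fraction` of its length lies in same-direction truth.
#' Centromeric Earlier-to-Later categories are collapsed onto
#' Earlier-to-Later for the comparison.
#'
#' @param called `feature_set` of RATs with a `category` column
#' @param truth truth object from [simulate_timing()] (or a data.frame of
#'   intervals with a `direction` column)
#' @param min_fraction required covered length fraction (0 < f <= 1)
#' @return list with `recall` and `precision` (precision NA when nothing
#'   was called)
#' @export
evaluate_recovery <- function(called, truth, min_fraction = 0.5) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  truth_df <- if (is.data.frame(truth)) truth else truth$rats
  norm_dir <- function(x) sub("-CEN$", "", x)
  cov_frac <- function(q_df, s_df) {
    if (nrow(s_df) == 0) return(rep(0, nrow(q_df)))
    s_gr <- GenomicRanges::reduce(features_granges(s_df))
    vapply(seq_len(nrow(q_df)), function(i) {
      q <- GenomicRanges::GRanges(q_df$chrom[i],
                                  IRanges::IRanges(q_df$start[i] + 1,
                                                   q_df$end[i]))
      al <- align_seqlevels(q, s_gr)
      sum(IRanges::width(GenomicRanges::intersect(al$a, al$b))) /
        (q_df$end[i] - q_df$start[i])
    }, numeric(1))
  }
  recall_hits <- vapply(seq_len(nrow(truth_df)), function(i) {
    same <- called[norm_dir(called$category) ==
                     norm_dir(truth_df$direction[i]), , drop = FALSE]
    cov_frac(truth_df[i, , drop = FALSE], same) >= min_fraction
  }, logical(1))
  recall <- if (nrow(truth_df)) mean(recall_hits) else NA_real_
  if (nrow(called) == 0)
    return(list(recall = recall, precision = NA_real_))
  prec_hits <- vapply(seq_len(nrow(called)), function(i) {
    same <- truth_df[norm_dir(truth_df$direction) ==
                       norm_dir(called$category[i]), , drop = FALSE]
    cov_frac(called[i, , drop = FALSE], same) >= min_fraction
  }, logical(1))
  list(recall = recall, precision = mean(prec_hits))
}

#' One-call synthetic Repli-seq study
#'
#' Convenience wrapper generating the default desk-scale dataset: genome and
#' annotations, injected compensated timing shifts plus the centromeric
#' mid-to-late template, a shared mappability field, and count tracks for
#' the 2C reference and both conditions' fraction replicates.
#'
#' @param config a [pipeline_config()]
#' @param n_chrom,chrom_length genome dimensions
#' @param depth reads per fraction sample
#' @param dispersion negative-binomial dispersion
#' @param n_replicates replicates per fraction
#' @param rat_magnitude injected timing-mass shift
#' @return list with `grid`, `features`, `timing`, `truth`, `mappability`,
#'   `reference`, `mitotic`, `endocycle`
#' @export
simulate_study <- function(config = pipeline_config(), n_chrom = 2,
                           chrom_length = 30e6, depth = 2e6,
                           dispersion = 0.05, n_replicates = 3,
                           rat_magnitude = 0.6) {
  seed <- config$seed
  gen <- make_genome(n_chrom, chrom_length, config$rt_window_size,
                     seed = stage_seed(seed, "genome"),
                     pericen_flank_bp = config$pericen_flank_bp)
  spec <- default_rat_spec(gen$grid, magnitude = rat_magnitude)
  tim <- simulate_timing(gen$grid, gen$features, spec,
                         seed = stage_seed(seed, "timing-master"))
  bl <- subset_features(gen$features, "blacklist")
  bl_mask <- rep(FALSE, n_windows(gen$grid))
  if (nrow(bl)) {
    for (i in seq_len(nrow(bl)))
      bl_mask[region_window_indices(gen$grid, bl$chrom[i], bl$start[i],
                                    bl$end[i])] <- TRUE
  }
  mapp <- make_mappability(gen$grid, bl_mask,
                           seed = stage_seed(seed, "mapp"))
  mito <- simulate_repliseq(tim$mitotic, gen$grid, mapp, depth, dispersion,
                            n_replicates, seed = stage_seed(seed, "mito"),
                            condition = "mitotic")
  endo <- simulate_repliseq(tim$endocycle, gen$grid, mapp, depth, dispersion,
                            n_replicates, seed = stage_seed(seed, "endo"),
                            condition = "endocycle")
  list(grid = gen$grid, features = gen$features, timing = tim,
       truth = tim$truth, mappability = mapp, reference = mito$reference,
       mitotic = mito$fractions, endocycle = endo$fractions)
}
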