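test_that("DRT is the signed endocycle-minus-mitotic difference", {
  g <- window_grid(c(chr1 = 9000), 3000)
  mito <- toy_profile(g, c(1, 1, 1), c(1, 1, 1), c(1, 1, 1))
  endo <- toy_profile(g, c(1, 1, 1), c(1, 1, 1), c(3, 1, 1))
  drt <- compute_drt(endo, mito)
  expect_equal(drt$diffs$L, c(2, 0, 0))
  expect_equal(drt$diffs$E, c(0, 0, 0))
  # identical profiles -> zero; swapped arguments -> negated
  expect_equal(compute_drt(mito, mito)$diffs$L, c(0, 0, 0))
  expect_equal(compute_drt(mito, endo)$diffs$L, -drt$diffs$L)
})

test_that("thresholds average per-chromosome extremes into a range", {
  g <- window_grid(c(chr1 = 6000, chr2 = 6000), 3000)
  mito <- toy_profile(g, rep(0, 4), rep(0, 4), rep(0, 4))
  # chr1 extremes (-1, +2); chr2 extremes (-3, +4)
  endo <- toy_profile(g, c(-1, 2, -3, 4), rep(0, 4), rep(0, 4))
  # M and L are flat here, so their degenerate ranges warn; E is the probe
  thr <- suppressWarnings(difference_thresholds(compute_drt(endo, mito)))
  e <- thr[thr$fraction == "E", ]
  expect_equal(e$avg_max_pos, 3)
  expect_equal(e$avg_max_neg, -2)
  expect_equal(e$range, 5)
  expect_equal(e$t_low, 0.5)
  expect_equal(e$t_high, 1.25)
  # symmetric +-d on one chromosome -> range 2d, t25 = d/2
  g1 <- window_grid(c(chr1 = 6000), 3000)
  endo2 <- toy_profile(g1, c(-2, 2), c(0, 0), c(0, 0))
  mito2 <- toy_profile(g1, c(0, 0), c(0, 0), c(0, 0))
  thr2 <- suppressWarnings(difference_thresholds(compute_drt(endo2, mito2)))
  expect_equal(thr2$range[1], 4)
  expect_equal(thr2$t_high[1], 1)
  # all-zero differences -> infinite thresholds, warning, no seeds
  expect_warning(thr0 <- difference_thresholds(compute_drt(mito, mito)),
                 "no window can seed")
  expect_true(all(!is.finite(thr0$t_low)))
  expect_equal(nrow(flag_compensated_windows(compute_drt(mito, mito), thr0)),
               0)
})

test_that("compensation requires an equal opposite shift in other fractions", {
  g <- window_grid(c(chr1 = 9000), 3000)
  drt <- structure(list(grid = g, mask = rep(FALSE, 3),
                        diffs = list(E = c(-1.2, -1.2, 0),
                                     M = c(0.5, -0.1, 0),
                                     L = c(0.8, 0.0, 0))),
                   class = "drt_track")
  thr <- data.frame(fraction = c("E", "M", "L"), avg_max_pos = 2,
                    avg_max_neg = -2, range = 4, t_low = 0.4, t_high = 1.0)
  fl <- flag_compensated_windows(drt, thr, "t_high")
  # window 1: |d_E| >= 1 and opposite sum 1.3 >= 1 -> flagged
  # window 2: no opposite-sign compensation -> not flagged
  # window 3: all zero -> never flagged
  expect_equal(fl$window, 1L)
  expect_equal(fl$fraction, "E")
  expect_equal(fl$sign, -1)
})

test_that("raising the threshold never adds flagged windows", {
  run <- default_study_run()
  fl_low <- run$calls$flags_low
  fl_high <- run$calls$flags_high
  expect_true(all(fl_high$window %in% fl_low$window))
  expect_gt(nrow(fl_low), nrow(fl_high))
})

test_that("gap merging follows bedtools -d semantics", {
  g <- window_grid(c(chr1 = 30000), 3000)
  # windows [0,3000) and [9000,12000): distance 6000 <= gap -> one interval
  m1 <- merge_flagged(c(1, 4), g, gap = 6000)
  expect_equal(nrow(m1), 1)
  expect_equal(c(m1$start, m1$end), c(0, 12000))
  # single window -> itself
  m2 <- merge_flagged(3, g, gap = 6000)
  expect_equal(c(m2$start, m2$end), c(6000, 9000))
  # distance 6600 > gap on a finer grid -> stays split
  g2 <- window_grid(c(chr1 = 30000), 600)
  m3 <- merge_flagged(c(1, 17), g2, gap = 6000)  # [0,600) and [9600,10200)
  expect_equal(nrow(m3), 2)
})

test_that("gap merging agrees with a brute-force pairwise merge", {
  set.seed(99)
  g <- window_grid(c(chrA = 200 * 3000, chrB = 200 * 3000), 3000)
  for (case in 1:1000) {
    k <- sample(1:12, 1)
    idx <- sort(sample.int(400, k))
    gap <- sample(c(0, 3000, 6000, 12000), 1)
    got <- merge_flagged(idx, g, gap)
    w <- g$windows[idx, , drop = FALSE]
    want <- brute_merge(w[, c("chrom", "start", "end")], gap)
    expect_equal(got$chrom, want$chrom)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("robust RATs need a >= 25% core and absorb adjacent 10% regions", {
  r10 <- feature_set("chr1", 0, 30000)
  r25 <- feature_set("chr1", 12000, 15000)
  rats <- build_rats(r10, r25)
  expect_equal(c(rats$start, rats$end), c(0, 30000))
  expect_true(all(rats$has_core25))
  # a 10% region with no core anywhere near it is discarded
  r10b <- feature_set(c("chr1", "chr1"), c(0, 100000), c(30000, 110000))
  rats2 <- build_rats(r10b, r25)
  expect_equal(nrow(rats2), 1)
  expect_equal(rats2$end, 30000)
  expect_equal(nrow(build_rats(feature_set(kind = character()),
                               feature_set(kind = character()))), 0)
})

test_that("direction classification is antisymmetric under condition swap", {
  g <- window_grid(c(chr1 = 9000), 3000)
  mito <- toy_profile(g, c(1.2, 1.2, 1.2), rep(1, 3), c(0.2, 0.2, 0.2))
  endo <- toy_profile(g, c(0.0, 0.0, 0.0), rep(1, 3), c(1.2, 1.2, 1.2))
  drt <- compute_drt(endo, mito)
  region <- list(chrom = "chr1", start = 0, end = 9000)
  expect_equal(classify_direction(region, drt), "Earlier-to-Later")
  expect_equal(classify_direction(region, compute_drt(mito, endo)),
               "Later-to-Earlier")
})

test_that("called RAT directions flip when the conditions are swapped", {
  run <- default_study_run()
  swapped <- call_rats(run$mito, run$endo, cen = run$cen, config = run$cfg)
  a <- run$calls$rats
  b <- swapped$rats
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$start, b$start)
  expect_equal(a$end, b$end)
  flip <- function(x) ifelse(grepl("^Earlier", x), "Later-to-Earlier",
                             "Earlier-to-Later")
  expect_equal(sub("-CEN$", "", b$category), flip(a$category))
})

test_that("every reported RAT contains a window flagged at the 25% level", {
  run <- default_study_run()
  rats <- run$calls$rats
  w <- run$calls$drt$grid$windows[run$calls$flags_high$window, ]
  for (i in seq_len(nrow(rats))) {
    hit <- w$chrom == rats$chrom[i] & w$start < rats$end[i] &
      w$end > rats$start[i]
    expect_true(any(hit))
  }
})

test_that("centromere overlap reclassifies Earlier-to-Later RATs only", {
  cen <- feature_set("chr1", 1.1e6, 2.0e6, kind = "CEN")
  rats <- feature_set(c("chr1", "chr1", "chr1"),
                      c(1.0e6, 1.2e6, 0.5e6),
                      c(1.2e6, 1.4e6, 0.6e6))
  rats$category <- c("Earlier-to-Later", "Later-to-Earlier",
                     "Earlier-to-Later")
  out <- annotate_cen(rats, cen)
  expect_equal(out$category,
               c("Earlier-to-Later-CEN", "Later-to-Earlier",
                 "Earlier-to-Later"))
  expect_equal(out$presumed_cen_bp, c(1e5, 0, 0))  # 100 kb outside the CEN
})

test_that("continuous CEN size bridges interspersed blacklist", {
  cen <- list(chrom = "chr1", start = 100000, end = 200000)
  rats <- feature_set(c("chr1", "chr1"), c(110000, 150000),
                      c(140000, 190000))
  bl <- feature_set("chr1", 140000, 150000, kind = "blacklist")
  s <- continuous_cen_size(rats, bl, cen)
  expect_equal(s$continuous_bp, 80000)
  expect_equal(s$pct_cen_covered, 80)
  expect_equal(s$cen_excl_blacklist_bp, 90000)
  expect_equal(s$rat_coverage_bp, 70000)
  # no RATs -> null summary rows
  s0 <- continuous_cen_size(rats[0, ], bl, cen)
  expect_true(is.na(s0$continuous_bp) && is.na(s0$pct_cen_covered))
  # RAT filling the whole CEN, no blacklist
  s1 <- continuous_cen_size(feature_set("chr1", 100000, 200000),
                            feature_set(kind = character()), cen)
  expect_equal(s1$continuous_bp, 100000)
  expect_equal(s1$pct_cen_covered, 100)
})

test_that("the RAT summary table reports count, median, coverage and %", {
  rats <- feature_set(rep("chr1", 3), c(0, 2e5, 5e5),
                      c(1e5, 3.5e5, 7e5))
  rats$category <- rep("Earlier-to-Later", 3)
  tab <- summarize_rats(rats, genome_size = 45e6)
  row <- tab[tab$category == "Earlier-to-Later", ]
  expect_equal(row$count, 3)
  expect_equal(row$median_size_kb, 150)
  expect_equal(row$coverage_kb, 450)
  expect_equal(row$pct_genome, 100 * 450e3 / 45e6)
  expect_equal(tab$count[tab$category == "Later-to-Earlier"], 0)
})
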