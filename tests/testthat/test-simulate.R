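test_that("make_genome tiles, centers centromeres and flanks pericentromeres", {
  gen <- make_genome(n_chrom = 2, chrom_length = 30e6, window_size = 3000,
                     seed = 4)
  expect_equal(n_windows(gen$grid), 20000)
  cen <- gen$features[gen$features$kind == "CEN" &
                        gen$features$chrom == "chr1", ]
  expect_equal(c(cen$start, cen$end), c(14e6, 16e6))
  peri <- gen$features[gen$features$kind == "pericentromere" &
                         gen$features$chrom == "chr1", ]
  expect_equal(sort(peri$start), c(13e6, 16e6))
  expect_equal(sort(peri$end), c(14e6, 17e6))
  # determinism and the flank-overflow guard
  gen2 <- make_genome(n_chrom = 2, chrom_length = 30e6, window_size = 3000,
                      seed = 4)
  expect_identical(gen$features, gen2$features)
  expect_error(make_genome(1, 3e6, 3000, cen_size = 1e6,
                           pericen_flank_bp = 2e6), "flank larger")
})

test_that("timing rows stay on the simplex and shifts move mass as stated", {
  gen <- make_genome(seed = 2, chrom_length = 3e6, cen_size = 4e5,
                     pericen_flank_bp = 2e5, n_genes = 20, n_tes = 10)
  spec <- data.frame(chrom = "chr1", start = 3e5, end = 4e5,
                     direction = "Earlier-to-Later", magnitude = 0.4)
  tim <- suppressWarnings(
    simulate_timing(gen$grid, gen$features, spec, seed = 3,
                    cen_shift = 0.5))
  expect_equal(rowSums(tim$mitotic), rep(1, n_windows(gen$grid)))
  expect_equal(rowSums(tim$endocycle), rep(1, n_windows(gen$grid)))
  expect_true(all(tim$mitotic >= 0) && all(tim$endocycle >= 0))
  idx <- repliRAT:::region_window_indices(gen$grid, "chr1", 3e5, 4e5)
  d <- tim$endocycle[idx, ] - tim$mitotic[idx, ]
  # Earlier-to-Later moves mass from early to late; mid untouched
  expect_true(all(d[, "pE"] <= 0))
  expect_equal(d[, "pM"], rep(0, length(idx)))
  expect_equal(d[, "pL"], -d[, "pE"])
  full <- tim$mitotic[idx, "pE"] >= 0.4
  expect_equal(unname(d[full, "pE"]), rep(-0.4, sum(full)))
  # the centromere gets a mid-to-late template shift
  cens <- gen$features[gen$features$kind == "CEN", ]
  ci_all <- unlist(lapply(seq_len(nrow(cens)), function(i)
    repliRAT:::region_window_indices(gen$grid, cens$chrom[i],
                                     cens$start[i], cens$end[i])))
  ci <- repliRAT:::region_window_indices(gen$grid, cens$chrom[1],
                                         cens$start[1], cens$end[1])
  dc <- tim$endocycle[ci, ] - tim$mitotic[ci, ]
  expect_true(all(dc[, "pM"] <= 0))
  expect_equal(dc[, "pL"], -dc[, "pM"])
  # windows outside all injected regions are identical in both conditions
  outside <- setdiff(seq_len(n_windows(gen$grid)), c(idx, ci_all))
  expect_equal(tim$endocycle[outside, ], tim$mitotic[outside, ])
  expect_error(simulate_timing(gen$grid, gen$features,
    rbind(spec, spec), seed = 1), "overlap")
})

test_that("simulated counts match their analytic means", {
  g <- window_grid(c(chr1 = 30 * 3000), 3000)
  timing <- matrix(1 / 3, 30, 3, dimnames = list(NULL, c("pE", "pM", "pL")))
  timing[1:10, ] <- matrix(rep(c(0.6, 0.3, 0.1), each = 10), 10)
  mapp <- rep(1, 30)
  depth <- 3e4
  sims <- lapply(1:200, function(s)
    simulate_repliseq(timing, g, mapp, depth = depth, dispersion = 0.05,
                      n_replicates = 1, seed = s)$fractions$E[[1]]$counts)
  emp <- colMeans(do.call(rbind, sims))
  lambda <- depth * timing[, 1] / sum(timing[, 1])
  se <- sqrt((lambda + 0.05 * lambda^2) / 200)
  expect_true(all(abs(emp - lambda) < 3 * se))
  # dispersion -> 0 gives Poisson-like variance
  sims0 <- vapply(1:200, function(s)
    simulate_repliseq(timing, g, mapp, depth = depth, dispersion = 0,
                      n_replicates = 1, seed = s)$fractions$E[[1]]$counts[1],
    numeric(1))
  expect_lt(var(sims0) / mean(sims0), 1.5)   # near-Poisson index
})

test_that("simulated totals concentrate around the requested depth", {
  run <- default_study_run()
  tot <- sum(run$study$mitotic$E[[1]]$counts)
  expect_lt(abs(tot - 2e6) / 2e6, 0.01)
})

test_that("blacklist windows fall below the 2.5% reference cutoff", {
  gen <- make_genome(seed = 8, chrom_length = 6e6, cen_size = 4e5,
                     pericen_flank_bp = 2e5, n_genes = 20, n_tes = 10)
  bl <- gen$features[gen$features$kind == "blacklist", ]
  bl_mask <- rep(FALSE, n_windows(gen$grid))
  for (i in seq_len(nrow(bl)))
    bl_mask[repliRAT:::region_window_indices(gen$grid, bl$chrom[i],
                                             bl$start[i], bl$end[i])] <- TRUE
  hits <- vapply(1:50, function(s) {
    mapp <- make_mappability(gen$grid, bl_mask, seed = s)
    ref <- simulate_repliseq(matrix(1 / 3, n_windows(gen$grid), 3),
                             gen$grid, mapp, depth = 2e5,
                             n_replicates = 1, seed = s)$reference
    mask <- detect_blacklist(ref)
    mean(mask[bl_mask])
  }, numeric(1))
  expect_gte(mean(hits), 0.95)
})

test_that("WGS pair simulation injects the requested CNV ratio", {
  g <- window_grid(c(chr1 = 100 * 5000), 5000)
  cnv <- data.frame(chrom = "chr1", start = 10 * 5000, end = 20 * 5000,
                    ratio = 2)
  sims <- lapply(1:300, function(s) simulate_wgs(g, cnv, depth = 5e4,
                                                 seed = s))
  ma <- colMeans(do.call(rbind, lapply(sims, function(x) x$a$counts)))
  mb <- colMeans(do.call(rbind, lapply(sims, function(x) x$b$counts)))
  expect_equal(mean(mb[11:20] / ma[11:20]), 2, tolerance = 0.1)
  expect_equal(mean(mb[-(11:20)] / ma[-(11:20)]), 1, tolerance = 0.05)
  # determinism
  expect_identical(simulate_wgs(g, cnv, 5e4, seed = 1)$b$counts,
                   simulate_wgs(g, cnv, 5e4, seed = 1)$b$counts)
})

test_that("ChIP simulation encodes the redeposition dilution", {
  g <- window_grid(c(chr1 = 2000 * 3000), 3000)
  region <- list(chrom = "chr1", start = 0, end = 40 * 3000)
  # full replacement at both rounds: 8C enrichment equals 2C's
  sim1 <- simulate_chip(g, region, enrichment = 10,
                        f_redeposition = c(1, 1), depth = 2e5, seed = 5)
  expect_equal(sim1$truth$expected_enrichment[["8C"]],
               sim1$truth$expected_enrichment[["2C"]])
  # no redeposition in the endocycle round: expected 8C/4C ratio 0.5
  sim2 <- simulate_chip(g, region, enrichment = 10,
                        f_redeposition = c(1, 0), depth = 2e5, seed = 5)
  expect_equal(sim2$truth$expected_enrichment[["8C"]] /
                 sim2$truth$expected_enrichment[["4C"]], 0.5)
  e8 <- enrichment_record(sim2$chip[["8C"]], sim2$input[["8C"]], region,
                          "8C")
  e4 <- enrichment_record(sim2$chip[["4C"]], sim2$input[["4C"]], region,
                          "4C")
  expect_equal(e8$mean / e4$mean, 0.5, tolerance = 0.05)
  # enrichment 1 (no binding): statistic ~ 1 at every ploidy
  sim3 <- simulate_chip(g, region, enrichment = 1,
                        f_redeposition = c(1, 1), depth = 2e5, seed = 5)
  for (pl in c("2C", "4C", "8C"))
    expect_equal(enrichment_record(sim3$chip[[pl]], sim3$input[[pl]],
                                   region, pl)$mean, 1, tolerance = 0.1)
})

test_that("recovery scoring uses same-direction length coverage", {
  truth <- data.frame(chrom = "chr1", start = 0, end = 1e5,
                      direction = "Earlier-to-Later")
  called <- feature_set("chr1", 0, 1e5)
  called$category <- "Earlier-to-Later"
  expect_equal(evaluate_recovery(called, truth, 0.5),
               list(recall = 1, precision = 1))
  # empty called set: recall 0, precision undefined
  r0 <- evaluate_recovery(called[0, ], truth, 0.5)
  expect_equal(r0$recall, 0)
  expect_true(is.na(r0$precision))
  # 60 of 100 kb covered in the same direction at min_fraction 0.5
  part <- feature_set("chr1", 20e3, 80e3)
  part$category <- "Earlier-to-Later"
  expect_equal(evaluate_recovery(part, truth, 0.5)$recall, 1)
  # wrong direction never counts
  part$category <- "Later-to-Earlier"
  expect_equal(evaluate_recovery(part, truth, 0.5)$recall, 0)
})
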