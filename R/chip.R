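#' Per-window ChIP fold enrichment over input
#'
#' ChIP replicates are summed, scaled to mean 1 over unmasked windows, and
#' divided by the likewise-scaled input. Unmasked windows with zero input
#' signal are added to the output mask.
#'
#' @param chip_reps list of ChIP `count_track`s (replicates)
#' @param input_track input `count_track` for the same ploidy
#' @param mask logical blacklist mask
#' @return a `signal_track` of fold enrichments
#' @export
window_fold_enrichment <- function(chip_reps, input_track, mask = NULL) {
  if (inherits(chip_reps, "count_track")) chip_reps <- list(chip_reps)
  grid <- chip_reps[[1]]$grid
  if (!same_grid(grid, input_track$grid)) stop("grid mismatch")
  if (is.null(mask)) mask <- rep(FALSE, n_windows(grid))
  summed <- count_track(grid, Reduce(`+`, lapply(chip_reps, `[[`, "counts")),
                        fraction = "chip",
                        ploidy = chip_reps[[1]]$meta$ploidy)
  chip_s <- scale_rpgc(summed, mask)
  input_s <- scale_rpgc(input_track, mask)
  suppressWarnings(normalize_to_reference(chip_s, input_s))
}

#' Region-level enrichment relative to DNA content
#'
#' The percent of total ChIP reads falling in the region divided by the
#' percent of total input reads in the region. Over the whole genome this is
#' exactly 1 for any sample pair.
#'
#' @param chip,input `count_track`s
#' @param region one interval (list/row with chrom, start, end)
#' @return enrichment value; NA with a warning when the input has no reads
#'   in the region
#' @export
region_enrichment <- function(chip, input, region) {
  idx <- region_window_indices(chip$grid, region$chrom, region$start,
                               region$end)
  chip_in <- sum(chip$counts[idx]); input_in <- sum(input$counts[idx])
  if (input_in == 0) {
    warning("no input reads in region; enrichment undefined")
    return(NA_real_)
  }
  (chip_in / sum(chip$counts)) / (input_in / sum(input$counts))
}

#' Region enrichment per replicate with summaries
#'
#' @param chip_reps list of ChIP `count_track` replicates
#' @param input_track input `count_track`
#' @param region one interval
#' @param ploidy ploidy label
#' @return list of class `enrichment_record`: `values` (per replicate),
#'   `mean`, `sd`, `ploidy`, `region`
#' @export
enrichment_record <- function(chip_reps, input_track, region,
                              ploidy = "none") {
  if (inherits(chip_reps, "count_track")) chip_reps <- list(chip_reps)
  vals <- vapply(chip_reps, region_enrichment, numeric(1),
                 input = input_track, region = region)
  structure(list(values = vals, mean = mean(vals),
                 sd = if (length(vals) > 1) stats::sd(vals) else NA_real_,
                 ploidy = ploidy, region = region),
            class = "enrichment_record")
}

#' Enrichment ratios between ploidy levels
#'
#' Ratio of mean enrichments (4C/2C and 8C/2C) with uncertainty from a
#' seeded bootstrap over replicate pairs: replicates are unpaired across
#' ploidies (separate sorts), so each resample draws one replicate value per
#' ploidy with replacement.
#'
#' @param records named list of `enrichment_record`s (names "2C", "4C",
#'   "8C"; "2C" required)
#' @param n_boot bootstrap resamples
#' @param seed integer seed
#' @return data.frame with columns comparison, ratio, boot_mean, boot_sd
#'   (NA rows for missing ploidies)
#' @export
ploidy_ratios <- function(records, n_boot = 1000, seed = 1L) {
  if (is.null(records[["2C"]])) stop("2C record required")
  if (records[["2C"]]$mean == 0) stop("zero 2C enrichment")
  set.seed(stage_seed(seed, "ploidy-boot"))
  one <- function(label) {
    rec <- records[[label]]
    if (is.null(rec))
      return(data.frame(comparison = paste0(label, "/2C"), ratio = NA_real_,
                        boot_mean = NA_real_, boot_sd = NA_real_))
    ratio <- rec$mean / records[["2C"]]$mean
    boots <- vapply(seq_len(n_boot), function(b) {
      mean(sample(rec$values, length(rec$values), replace = TRUE)) /
        mean(sample(records[["2C"]]$values, length(records[["2C"]]$values),
                    replace = TRUE))
    }, numeric(1))
    data.frame(comparison = paste0(label, "/2C"), ratio = ratio,
               boot_mean = mean(boots), boot_sd = stats::sd(boots))
  }
  rbind(one("4C"), one("8C"))
}

#' Expected enrichment ratio under the redeposition model
#'
#' Each replication round doubles the DNA while the existing centromeric
#' histone complement carries over; a fraction f of the resulting deficit is
#' redeposited, multiplying the enrichment-per-DNA-content by (1 + f)/2 per
#' round. f = 1 (full replacement) leaves enrichment unchanged; f = 0 (no
#' redeposition) halves it per round.
#'
#' @param f per-round redeposited deficit fraction(s); scalar recycled over
#'   `rounds`, or a vector with one value per round
#' @param rounds number of replication rounds (ignored when `f` has length
#'   > 1)
#' @return expected enrichment ratio relative to the pre-replication value
#' @export
expected_ratio <- function(f, rounds = 1) {
  if (length(f) == 1) f <- rep(f, rounds)
  stopifnot(all(f >= 0 & f <= 1))
  prod((1 + f) / 2)
}

#' Infer the redeposition fraction from an observed ratio (one round)
#'
#' Inverts the per-round model: f = 2 x ratio - 1, clipped to [0, 1] with a
#' flag when clipping occurred.
#'
#' @param observed_ratio observed enrichment ratio (> 0)
#' @return list with `f` and `clipped`
#' @export
infer_redeposition <- function(observed_ratio) {
  stopifnot(observed_ratio > 0)
  f <- 2 * observed_ratio - 1
  clipped <- f < 0 || f > 1
  list(f = min(max(f, 0), 1), clipped = clipped)
}
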