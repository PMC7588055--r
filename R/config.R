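#' Pipeline configuration
#'
#' Collects every tunable parameter of the pipeline with its default. All
#' randomness flows from `seed`: each stage draws from a named substream
#' derived deterministically from it (see [stage_seed()]).
#'
#' @param rt_window_size replication-timing window size in bp
#' @param cn_window_size copy-number screening window size in bp
#' @param cen_window_size centromere summary window size in bp
#' @param threshold_low,threshold_high DRT thresholds as percent of the total
#'   difference range (defaults 10 and 25)
#' @param gap_bp merge gap distance in bp for RAT calling
#' @param seed_fractions S-phase fractions allowed to seed a RAT window
#'   (default early and late; mid contributes through compensation)
#' @param n_permutations shuffle count for permutation tests
#' @param pericen_flank_bp pericentromere flank width in bp
#' @param min_element_overlap_bp minimum single-window overlap for an element
#'   to enter feature-level replication-timing summaries
#' @param downsample_target optional read total to downsample each sample to
#'   (NULL = no downsampling)
#' @param wavelet_level Haar smoothing level (number of finest detail bands
#'   zeroed)
#' @param keep_percentiles blacklist keep range (low, high) in percent
#' @param seed master random seed
#' @return a list of class `pipeline_config`
#' @export
pipeline_config <- function(rt_window_size = 3000,
                            cn_window_size = 5000,
                            cen_window_size = 100000,
                            threshold_low = 10,
                            threshold_high = 25,
                            gap_bp = 6000,
                            seed_fractions = c("E", "L"),
                            n_permutations = 1000,
                            pericen_flank_bp = 1000000,
                            min_element_overlap_bp = 1500,
                            downsample_target = NULL,
                            wavelet_level = 3,
                            keep_percentiles = c(2.5, 100),
                            seed = 1L) {
  cfg <- list(rt_window_size = rt_window_size,
              cn_window_size = cn_window_size,
              cen_window_size = cen_window_size,
              threshold_low = threshold_low,
              threshold_high = threshold_high,
              gap_bp = gap_bp,
              seed_fractions = match.arg(seed_fractions, c("E", "M", "L"),
                                         several.ok = TRUE),
              n_permutations = n_permutations,
              pericen_flank_bp = pericen_flank_bp,
              min_element_overlap_bp = min_element_overlap_bp,
              downsample_target = downsample_target,
              wavelet_level = wavelet_level,
              keep_percentiles = keep_percentiles,
              seed = as.integer(seed))
  stopifnot(cfg$threshold_low > 0, cfg$threshold_high > 0,
            cfg$gap_bp >= 0, cfg$n_permutations >= 1,
            cfg$wavelet_level >= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Keys present in the file override [pipeline_config()] defaults; unknown
#' keys are an error.
#' @param path YAML file
#' @return a `pipeline_config`
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Deterministic per-stage seed
#'
#' Derives a reproducible 31-bit substream seed from the master seed and a
#' stage name, so that changing e.g. the number of permutations never
#' perturbs an unrelated stage's draws.
#' @param seed master integer seed
#' @param stage stage name (character)
#' @return an integer seed
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 1009) %% 2147483647)
}
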