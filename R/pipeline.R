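#' Run the full replication-timing comparison pipeline
#'
#' Validates the sample manifest, builds replication profiles for both
#' conditions from a shared 2C reference, calls RATs, and writes every
#' intermediate and summary product under `out_dir`: smoothed signal
#' bedGraphs, blacklist BED, per-fraction DRT bedGraphs, RAT BED (name =
#' category, score = mean |DRT| rescaled to 0-1000), a thresholds JSON, a
#' category summary TSV (count / median size / coverage / % of genome),
#' an optional centromere summary TSV, a replicate-correlation TSV, and a
#' log of the seed and thresholds actually used.
#'
#' @param config a [pipeline_config()]
#' @param manifest list with `reference` (a `count_track` or bedGraph path)
#'   and `mitotic` / `endocycle` (each a named list `E`, `M`, `L` of
#'   `count_track`s, lists of replicate `count_track`s, or paths); optional
#'   `cen` (`feature_set` or BED path)
#' @param out_dir output directory (created if needed); NULL skips writing
#' @param grid `window_grid`, required when the manifest contains paths
#' @return list with `profiles`, `calls` (from [call_rats()]), `summary`,
#'   `cen_summary`, `correlations`
#' @export
run_pipeline <- function(config, manifest, out_dir = NULL, grid = NULL) {
  for (cond in c("mitotic", "endocycle")) {
    if (is.null(manifest[[cond]]))
      stop("configuration error: manifest lacks condition '", cond, "'")
    for (f in c("E", "M", "L"))
      if (is.null(manifest[[cond]][[f]]))
        stop("configuration error: manifest lacks ", cond, " ", f,
             " track")
  }
  if (is.null(manifest$reference))
    stop("configuration error: manifest lacks the 2C reference track")

  resolve <- function(x, ...) {
    if (inherits(x, "count_track")) return(list(x))
    if (is.character(x)) return(lapply(x, read_count_track, grid = grid, ...))
    lapply(x, function(el)
      if (is.character(el)) read_count_track(el, grid, ...) else el)
  }
  reference <- resolve(manifest$reference, fraction = "reference")[[1]]
  tracks <- lapply(c(mitotic = "mitotic", endocycle = "endocycle"),
                   function(cond)
                     lapply(c(E = "E", M = "M", L = "L"), function(f)
                       resolve(manifest[[cond]][[f]])))
  if (!is.null(config$downsample_target)) {
    k <- 0
    for (cond in names(tracks)) for (f in names(tracks[[cond]]))
      tracks[[cond]][[f]] <- lapply(tracks[[cond]][[f]], function(tr) {
        k <<- k + 1
        downsample(tr, config$downsample_target,
                   seed = stage_seed(config$seed, paste0("ds", k)))
      })
  }
  profiles <- lapply(c(mitotic = "mitotic", endocycle = "endocycle"),
                     function(cond)
                       build_profile(reference, tracks[[cond]],
                                     condition = cond,
                                     level = config$wavelet_level,
                                     keep_percentiles =
                                       config$keep_percentiles))
  cen <- manifest$cen
  if (is.character(cen)) cen <- read_features(cen, kind = "CEN")
  calls <- call_rats(profiles$endocycle, profiles$mitotic, cen = cen,
                     config = config)
  genome_size <- sum(reference$grid$chromosomes)
  summary_tab <- summarize_rats(calls$rats, genome_size)
  cen_summary <- NULL
  if (!is.null(cen) && nrow(cen)) {
    bl <- blacklist_features(reference$grid, profiles$mitotic$mask)
    cen_summary <- do.call(rbind, lapply(seq_len(nrow(cen)), function(i) {
      in_cen <- calls$rats[calls$rats$category == "Earlier-to-Later-CEN" &
                             calls$rats$chrom == cen$chrom[i], ,
                           drop = FALSE]
      if (nrow(in_cen)) {
        ov <- in_cen$start < cen$end[i] & in_cen$end > cen$start[i]
        in_cen <- in_cen[ov, , drop = FALSE]
      }
      cbind(data.frame(cen = paste0(cen$chrom[i], ":", cen$start[i], "-",
                                    cen$end[i])),
            continuous_cen_size(in_cen, bl, cen[i, ]))
    }))
  }
  correlations <- lapply(c(mitotic = "mitotic", endocycle = "endocycle"),
                         function(cond) {
    sapply(c(E = "E", M = "M", L = "L"), function(f) {
      reps <- tracks[[cond]][[f]]
      if (length(reps) < 2) return(NA_real_)
      r <- replicate_correlation(reps)
      mean(r[upper.tri(r)])
    })
  })
  out <- list(profiles = profiles, calls = calls, summary = summary_tab,
              cen_summary = cen_summary, correlations = correlations)
  if (!is.null(out_dir)) write_pipeline_outputs(out, config, out_dir)
  invisible(out)
}

blacklist_features <- function(grid, mask) {
  if (!any(mask)) return(feature_set(kind = character()))
  w <- grid$windows[mask, , drop = FALSE]
  gr <- GenomicRanges::reduce(
    GenomicRanges::GRanges(w$chrom, IRanges::IRanges(w$start + 1, w$end)))
  granges_features(gr, kind = "blacklist")
}

write_pipeline_outputs <- function(out, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  for (cond in names(out$profiles))
    for (f in c("E", "M", "L"))
      write_track(out$profiles[[cond]]$tracks[[f]],
                  p(sprintf("profile_%s_%s.bedgraph", cond, f)))
  bl <- blacklist_features(out$profiles$mitotic$grid,
                           out$profiles$mitotic$mask)
  if (nrow(bl)) write_features(bl, p("blacklist.bed"))
  drt <- out$calls$drt
  for (f in c("E", "M", "L")) {
    tr <- signal_track(drt$grid, ifelse(drt$mask, 0, drt$diffs[[f]]),
                       drt$mask)
    write_track(tr, p(sprintf("drt_%s.bedgraph", f)))
  }
  rats <- out$calls$rats
  if (nrow(rats)) {
    mean_abs <- rowMeans(abs(as.matrix(
      rats[, c("mean_drt_E", "mean_drt_M", "mean_drt_L")])), na.rm = TRUE)
    score <- if (max(mean_abs) > 0) 1000 * mean_abs / max(mean_abs) else 0
    write_features(rats, p("rats.bed"), names = rats$category,
                   scores = score)
  }
  jsonlite::write_json(
    list(seed = config$seed,
         threshold_low_pct = config$threshold_low,
         threshold_high_pct = config$threshold_high,
         gap_bp = config$gap_bp,
         wavelet_level = config$wavelet_level,
         thresholds = out$calls$thresholds),
    p("thresholds.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.table(out$summary, p("rat_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(out$cen_summary))
    utils::write.table(out$cen_summary, p("cen_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  corr <- do.call(rbind, lapply(names(out$correlations), function(cond)
    data.frame(condition = cond, fraction = names(out$correlations[[cond]]),
               mean_pearson_r = unname(out$correlations[[cond]]))))
  utils::write.table(corr, p("replicate_correlation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(c(sprintf("seed: %d", config$seed),
               sprintf("threshold_low: %g%%", config$threshold_low),
               sprintf("threshold_high: %g%%", config$threshold_high),
               sprintf("gap_bp: %d", config$gap_bp),
               sprintf("wavelet_level: %d", config$wavelet_level)),
             p("pipeline.log"))
  invisible(out_dir)
}
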