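#' Analysis configuration
#'
#' One source of truth for every tunable of the pipeline, with defaults
#' fixed at the values used throughout the analysis: Gaussian smoothing
#' sigma 1 px, 2x2 average pooling, 5th-percentile F0, 5\% dF/F0 event
#' threshold, 0.5 px motion threshold, 1000 seeds, 0.95 region threshold,
#' 0.997 pooling correlation, 2\% response criterion, stimulation window
#' frames 11-15, response window frames 11-20, baseline frames 1-10.
#' Frame windows are quoted 1-based inclusive, matching the convention used
#' in the rest of the package (R indexing is 1-based throughout).
#'
#' @param ... overrides for any default field.
#' @return An `AnalysisConfig` list.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    frame_rate = 10,
    smooth_sigma = 1,
    pool = 2L,
    f0_percentile = 5,
    event_threshold = 0.05,
    event_smooth_k = 5L,
    motion_threshold = 0.5,
    seed_count = 1000L,
    region_threshold = 0.95,
    band_threshold = 0.6,
    pooling_correlation = 0.997,
    response_criterion = 0.02,
    search_window = c(11L, 15L),
    response_window = c(11L, 20L),
    baseline_window = c(1L, 10L),
    svd_var_fraction = 0.9,
    diffusion_t = 1,
    seed = 1L,
    movie_path = NULL,
    mask_path = NULL,
    out_dir = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  structure(cfg, class = "AnalysisConfig")
}

#' Write / read an analysis configuration
#'
#' YAML serialization mirroring the `AnalysisConfig` field names; unknown
#' keys in a file are rejected and defaults round-trip unchanged.
#'
#' @param cfg an [analysis_config()].
#' @param path file path.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "AnalysisConfig"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(analysis_config, raw[!vapply(raw, is.null, logical(1))])
  # preserve storage modes so a write/read cycle is exact
  ref <- analysis_config()
  for (k in names(cfg)) {
    if (!is.null(cfg[[k]]) && !is.null(ref[[k]]) && is.numeric(ref[[k]]))
      storage.mode(cfg[[k]]) <- storage.mode(ref[[k]])
  }
  cfg
}

window_seq <- function(w) seq.int(w[1L], w[2L])

# Run manifest: every parameter plus software versions; no timestamps, so
# reruns with identical inputs are byte-identical.
write_manifest <- function(cfg, extra, path) {
  man <- list(config = unclass(cfg),
              package_version = as.character(utils::packageVersion("icbands")),
              r_version = paste(R.version$major, R.version$minor, sep = "."))
  man <- c(man, extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' End-to-end spontaneous-activity analysis
#'
#' Runs the full preprocessing chain, the line-scan event analysis on the
#' left hemisphere, the bilateral correlation statistics (representative
#' seeds and SbBC), the region morphology of the low-frequency seed, and
#' the diffusion-map embedding. All tabular outputs plus a machine-readable
#' run manifest are written under `out_dir` when given.
#'
#' @param config an [analysis_config()].
#' @param movie raw [movie_stack()]; read from `config$movie_path` when
#'   omitted.
#' @param masks [roi_mask_set()]; read from `config$mask_path` when omitted.
#' @return List with `summary`, `catalog`, `bilateral`, `region`,
#'   `embedding`, `preprocessed`.
#' @export
run_spontaneous_pipeline <- function(config = analysis_config(),
                                     movie = NULL, masks = NULL) {
  stopifnot(inherits(config, "AnalysisConfig"))
  if (is.null(movie)) movie <- read_movie_tiff(config$movie_path,
                                               config$frame_rate)
  if (is.null(masks)) masks <- read_mask_tiff(config$mask_path)
  if (!any(masks$outside))
    stop("mask set has no outside-ROI label: the partial-correlation ",
         "control regressor requires pixels outside the IC", call. = FALSE)

  pp <- preprocess_movie(movie, masks,
                         smooth_sigma = config$smooth_sigma,
                         svd_var_fraction = config$svd_var_fraction,
                         f0_percentile = config$f0_percentile,
                         motion_threshold = config$motion_threshold)
  dff <- pp$movie; dmask <- pp$masks

  # line-scan events over the left hemisphere bounding box
  lb <- which(dmask$left, arr.ind = TRUE)
  rect <- c(min(lb[, 1L]), min(lb[, 2L]), max(lb[, 1L]), max(lb[, 2L]))
  ls <- compute_line_scan(dff, rect, angle = 0)
  cat <- detect_band_peaks(ls, amp_threshold = config$event_threshold,
                           smooth_k = config$event_smooth_k)
  cat <- censor_motion_events(cat, pp$motion)
  summ <- summarize_events(cat)

  seeds <- select_representative_seeds(dff, dmask, pp$motion,
                                       grid = build_seed_grid(dim(dff)[1:2],
                                                              config$seed_count,
                                                              dmask),
                                       band_threshold = config$band_threshold)
  bil <- bilateral_stats(dff, dmask, pp$motion, seeds)
  region <- NULL
  if (!is.null(seeds$low)) {
    lowmap <- seed_correlation_map(dff, seeds$low, dmask, pp$motion)
    region <- tryCatch(
      correlation_region_properties(lowmap, dmask$left,
                                    threshold = config$region_threshold),
      error = function(e) NULL)
  }
  emb <- diffusion_map(dff, dmask, t = config$diffusion_t)

  out <- list(summary = summ, catalog = cat, bilateral = bil,
              region = region, embedding = emb, preprocessed = pp)
  if (!is.null(config$out_dir)) write_spont_outputs(out, config)
  out
}

write_spont_outputs <- function(res, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  utils::write.csv(as.data.frame(res$summary), p("event_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(res$catalog)),
                   p("event_catalog.csv"), row.names = FALSE)
  bil <- res$bilateral
  utils::write.csv(data.frame(statistic = c("global_r", "sbbc_low",
                                            "sbbc_mid", "sbbc_high",
                                            "sbbc_avg"),
                              value = c(bil$global_r, bil$sbbc, bil$sbbc_avg)),
                   p("bilateral_stats.csv"), row.names = FALSE)
  if (!is.null(res$region))
    utils::write.csv(data.frame(eccentricity = res$region$eccentricity,
                                proportion = res$region$proportion,
                                area_px = res$region$area_px),
                     p("region_props.csv"), row.names = FALSE)
  utils::write.csv(cbind(res$embedding$pixels, res$embedding$coords),
                   p("embedding.csv"), row.names = FALSE)
  write_manifest(config,
                 list(bleach = unclass(res$preprocessed$bleach),
                      svd_rank = attr(res$preprocessed$movie, "svd_rank")),
                 p("manifest.json"))
  invisible(res)
}

#' End-to-end evoked-threshold analysis
#'
#' Preprocesses each session movie (the full chain minus dF/F0
#' normalization), averages trials across sessions per frequency-SPL
#' condition, normalizes to dF/F0 against the pre-stimulus baseline,
#' extracts pooled response curves, calls per-frequency thresholds, and
#' renders mean response images.
#'
#' @param config an [analysis_config()].
#' @param sessions list of sessions (`movie` + trial `log`), e.g. from
#'   [generate_evoked_session()].
#' @param protocol the [build_stimulus_protocol()] the sessions follow.
#' @param masks [roi_mask_set()] on the raw grid, required when
#'   `preprocess = TRUE`; defaults to the first session's `masks` element.
#' @param preprocess run the per-session preprocessing chain (recommended;
#'   trial averaging alone does not remove pixel noise that the smoothing,
#'   pooling and SVD steps do).
#' @return List with `thresholds` (a `ThresholdTable`), `images` (named list
#'   of response images), `tensor`.
#' @export
run_evoked_pipeline <- function(config = analysis_config(), sessions,
                                protocol, masks = NULL, preprocess = TRUE) {
  stopifnot(inherits(config, "AnalysisConfig"))
  fpt <- protocol$frames_per_trial
  for (s in sessions) {
    if (n_frames(s$movie) < max(s$log$start_frame) + fpt - 1L)
      stop("session movie shorter than its trial log", call. = FALSE)
  }
  if (preprocess) {
    masks <- masks %||% sessions[[1L]]$masks
    if (is.null(masks))
      stop("preprocessing requires a mask set", call. = FALSE)
    sessions <- lapply(sessions, function(s) {
      pp <- suppressWarnings(
        preprocess_movie(s$movie, masks,
                         smooth_sigma = config$smooth_sigma,
                         svd_var_fraction = config$svd_var_fraction,
                         f0_percentile = config$f0_percentile,
                         motion_threshold = config$motion_threshold,
                         normalize = FALSE))
      list(movie = pp$movie, log = s$log)
    })
  }
  tensor <- average_trials(sessions, protocol)
  tensor <- evoked_dff(tensor, window_seq(config$baseline_window))
  thr <- threshold_table(tensor, protocol,
                         criterion = config$response_criterion,
                         window = window_seq(config$response_window),
                         corr_threshold = config$pooling_correlation,
                         search_frames = window_seq(config$search_window))
  imgs <- lapply(tensor$entries, response_image,
                 frames = window_seq(config$search_window))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(unclass(thr)),
                     file.path(config$out_dir, "threshold_table.csv"),
                     row.names = FALSE)
    write_manifest(config, list(n_sessions = length(sessions)),
                   file.path(config$out_dir, "manifest.json"))
  }
  list(thresholds = thr, images = imgs, tensor = tensor)
}
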