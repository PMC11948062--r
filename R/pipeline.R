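#' Pipeline configuration
#'
#' All tunable settings of the end-to-end pipeline in one validated object.
#' The defaults reproduce the clinical protocol: 200-frame blocks with 5
#' removed singular components, a 2-wavelength linking gate with a minimum
#' track duration of 1 frame, 10x map upsampling, a 20 degree dispersity
#' threshold and the 1/5/95/99 velocity percentile set.
#'
#' @param meta An [acquisition_meta()].
#' @param block_length,n_remove Clutter filter settings, see
#'   [filter_params()].
#' @param threshold_k,min_separation_px,patch_halfwidth Detection settings,
#'   see [localize_stack()].
#' @param max_link_distance,min_duration Linking settings, see
#'   [link_tracks()]; `max_link_distance = NULL` means `2 * wavelength`.
#' @param upsampling_factor Map upsampling factor.
#' @param angle_threshold Dispersity direction-change threshold (degrees).
#' @param percentiles Velocity percentile set.
#' @param tic_level,tic_n_starts TIC settings, see [fit_bolus()].
#' @param seed Global seed; per-stage seeds derive from it deterministically.
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(meta = acquisition_meta(),
                            block_length = 200L, n_remove = 5L,
                            threshold_k = 4, min_separation_px = NULL,
                            patch_halfwidth = 2L,
                            max_link_distance = NULL, min_duration = 1L,
                            upsampling_factor = 10L,
                            angle_threshold = 20,
                            percentiles = c(1, 5, 95, 99),
                            tic_level = 0.1, tic_n_starts = 10L,
                            seed = 1L) {
  validate_meta(meta)
  filter_params(block_length, n_remove)   # validates
  cfg <- list(meta = meta, block_length = as.integer(block_length),
              n_remove = as.integer(n_remove),
              threshold_k = as.numeric(threshold_k),
              min_separation_px = min_separation_px,
              patch_halfwidth = as.integer(patch_halfwidth),
              max_link_distance = max_link_distance,
              min_duration = as.integer(min_duration),
              upsampling_factor = as.integer(upsampling_factor),
              angle_threshold = as.numeric(angle_threshold),
              percentiles = as.numeric(unlist(percentiles)),
              tic_level = as.numeric(tic_level),
              tic_n_starts = as.integer(tic_n_starts),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config\n")
  cat(sprintf("  filter: blocks of %d frames, %d components removed\n",
              x$block_length, x$n_remove))
  gate <- x$max_link_distance %||% (2 * x$meta$wavelength)
  cat(sprintf("  linking: gate %.3f mm, min duration %d frame(s)\n",
              gate, x$min_duration))
  cat(sprintf("  maps: %dx upsampling; dispersity threshold %g deg\n",
              x$upsampling_factor, x$angle_threshold))
  cat(sprintf("  percentiles: %s; seed %d\n",
              paste(x$percentiles, collapse = "/"), x$seed))
  invisible(x)
}

#' Write / read a pipeline configuration (YAML)
#'
#' The round trip is lossless: `read_config(write_config(cfg, f))` equals
#' `cfg`.
#'
#' @param config A [pipeline_config()].
#' @param path YAML path.
#' @return The path (write) or a `pipeline_config` (read).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  m <- config$meta
  lst <- unclass(config)
  lst$meta <- list(pixel_pitch_axial = m$pixel_pitch_axial,
                   pixel_pitch_lateral = m$pixel_pitch_lateral,
                   frame_rate = m$frame_rate,
                   transmit_frequency = m$transmit_frequency,
                   sound_speed = m$sound_speed)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  meta <- do.call(acquisition_meta, lst$meta)
  lst$meta <- NULL
  lst <- lst[!vapply(lst, is.null, logical(1))]
  do.call(pipeline_config, c(list(meta = meta), lst))
}

#' Run the full ULM pipeline on a clip
#'
#' Clip -> SVD clutter filter -> localization -> tracking -> maps -> track
#' metrics -> whole-field TIC, writing every artifact plus a run manifest to
#' `outdir`. Identical input, config and seed give identical outputs.
#'
#' @param input A [frame_stack()] or the path of a TIFF clip written by
#'   [write_frame_stack()].
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if missing).
#' @param fit_tic Also extract and fit the whole-field TIC (default TRUE;
#'   fitting is skipped with a note when the clip carries no bolus
#'   dynamics).
#' @return Invisibly, a list with the in-memory stage results
#'   (`filtered`, `localizations`, `tracks`, `maps`, `metrics`, `tic`,
#'   `bolus_fit`) and `manifest` (also written as `manifest.json`).
#' @export
run_pipeline <- function(input, config = pipeline_config(), outdir,
                         fit_tic = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  stack <- if (is.character(input)) read_frame_stack(input) else input
  stopifnot(inherits(stack, "frame_stack"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("failed at stage '%s': %s", name,
                         conditionMessage(e)),
                 file.path(outdir, "FAILED"))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  fp <- filter_params(config$block_length, config$n_remove)
  filtered <- stage("clutter_filter", svd_filter(stack, fp))
  locs <- stage("localization",
                localize_stack(filtered, threshold_k = config$threshold_k,
                               min_separation_px = config$min_separation_px,
                               patch_halfwidth = config$patch_halfwidth))
  tracks <- stage("tracking",
                  link_tracks(locs, stack$meta,
                              max_link_distance = config$max_link_distance,
                              min_duration = config$min_duration))
  maps <- stage("mapping",
                accumulate_maps(tracks, stack$meta,
                                factor = config$upsampling_factor))
  metrics <- stage("track_metrics",
                   track_metrics(tracks, stack$meta,
                                 angle_threshold = config$angle_threshold))
  tic <- stage("tic_extract",
               extract_tic(stack, matrix(TRUE, dim(stack)[2], dim(stack)[3]),
                           roi = "whole_field"))
  bolus <- NULL
  if (fit_tic) {
    bolus <- tryCatch(fit_bolus(tic, n_starts = config$tic_n_starts,
                                seed = derive_seed(config$seed, "tic"),
                                level = config$tic_level),
                      bolus_fit_error = function(e) NULL)
  }
  ## artifacts
  write_localizations(locs, file.path(outdir, "localizations.csv"))
  write_tracks(tracks, file.path(outdir, "tracks.csv"))
  map_files <- write_maps(maps, file.path(outdir, "map"))
  utils::write.csv(metrics, file.path(outdir, "track_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(tic), file.path(outdir, "tic.csv"),
                   row.names = FALSE)
  if (!is.null(bolus)) {
    write_tic_params(bolus, file.path(outdir, "tic_params.csv"))
  }
  cfg_file <- file.path(outdir, "config.yaml")
  write_config(config, cfg_file)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ulmpipe")),
    seed = config$seed,
    config_sha = unname(tools::md5sum(cfg_file)),
    n_frames_in = n_frames(stack),
    n_frames_filtered = n_frames(filtered),
    n_localizations = nrow(locs),
    n_tracks = length(unique(tracks$track_id)),
    n_track_points = nrow(tracks),
    map_total_counts = sum(maps$density),
    tic_fitted = !is.null(bolus),
    artifacts = c("localizations.csv", "tracks.csv", basename(map_files),
                  "track_metrics.csv", "tic.csv",
                  if (!is.null(bolus)) "tic_params.csv", "config.yaml"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(filtered = filtered, localizations = locs, tracks = tracks,
                 maps = maps, metrics = metrics, tic = tic,
                 bolus_fit = bolus, manifest = manifest))
}

#' Phantom-based pipeline self-test
#'
#' Generates the standard validation phantoms, runs the pipeline on them and
#' evaluates the battery of recovery checks (clutter rejection, velocity
#' recovery at the grey-matter flow scale, sub-wavelength two-vessel
#' separation, TIC parameter recovery, grid constant). Results go to a
#' machine-readable JSON report; failures are report entries, not errors.
#'
#' @param outdir Directory for the report (created if missing).
#' @param seed Integer seed for all phantom randomness.
#' @return Invisibly, a data.frame with one row per check: `check`,
#'   `measured`, `expected`, `tolerance`, `pass`.
#' @export
selftest <- function(outdir, seed = 1L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  checks <- list()
  add <- function(check, measured, expected, tolerance) {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, measured = measured, expected = expected,
      tolerance = tolerance,
      pass = is.finite(measured) && abs(measured - expected) <= tolerance)
  }
  meta <- acquisition_meta()

  ## fine-grid constant
  maps <- accumulate_maps(new_track_set(
    data.frame(track_id = integer(0), frame = integer(0),
               axial_mm = numeric(0), lateral_mm = numeric(0)),
    meta, 2 * meta$wavelength, 1L), meta, factor = 10L)
  add("fine_pixel_um", unname(maps$fine_pitch[1]) * 1000, 10, 1e-9)

  ## clutter rejection
  cr <- measure_clutter_rejection(seed = derive_seed(seed, "clutter"))
  add("clutter_residual_fraction", cr, 0, 1e-3)

  ## velocity recovery at 4 mm/s
  vr <- measure_velocity_recovery(seed = derive_seed(seed, "velocity"))
  add("median_velocity_mm_s", vr$median_velocity, 4, 0.4)

  ## sub-wavelength vessel separation
  sep <- measure_vessel_separation(seed = derive_seed(seed, "separation"))
  add("ridge_separation_mm", sep$separation_mm, 0.2, 0.03)

  ## TIC recovery
  tr <- measure_tic_recovery(seed = derive_seed(seed, "tic"))
  add("tic_ttp_s", tr$TTP, tr$TTP_true, 0.01 * tr$TTP_true)

  report <- do.call(rbind, checks)
  jsonlite::write_json(report, file.path(outdir, "selftest.json"),
                       dataframe = "rows", auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(report)
}
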