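#' Read and write inertial recordings (CSV plus sidecar JSON)
#'
#' Recordings are stored as a plain CSV with header `t,ax,ay,az,vx,vy,vz`
#' and a sidecar JSON (`<path>.json`) holding the metadata (`subject_id`,
#' `trial_label`, `fs`, units, schema version). The pair round-trips
#' losslessly; a recording with missing samples is rejected at load time.
#'
#' @param recording A [lift_recording()].
#' @param path CSV file path (the sidecar is written next to it).
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns a [lift_recording()].
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "lift_recording"))
  readr::write_csv(tibble::as_tibble(recording), path, progress = FALSE)
  meta <- list(
    subject_id = attr(recording, "subject_id"),
    trial_label = attr(recording, "trial_label"),
    fs = attr(recording, "fs"),
    units = list(acceleration = "m/s^2", angular_velocity = "rad/s", t = "s"),
    schema = "liftrisk-recording-v1"
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) abort(sprintf("recording file not found: %s", path))
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) abort(sprintf("sidecar metadata not found: %s", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  lift_recording(dat, fs = meta$fs, subject_id = meta$subject_id,
                 trial_label = meta$trial_label)
}

#' Read and write region-of-interest tables
#'
#' ROI tables are CSV with columns
#' `subject,trial,lift_index,start,end,start_s,end_s` (0-based, half-open
#' sample intervals).
#'
#' @param rois ROI tibble (from [segment_recording()] or ground truth).
#' @param path CSV file path.
#' @export
write_rois <- function(rois, path) {
  readr::write_csv(rois, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  if (!file.exists(path)) abort(sprintf("ROI file not found: %s", path))
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Run the full classification pipeline on a synthetic cohort
#'
#' End-to-end chain reproducing the study's analysis on generated data:
#' simulate a cohort ([generate_cohort()]), segment every recording
#' ([segment_recording()]), assemble the 114-column feature table
#' ([build_feature_table()]), screen features ([screen_features()]), prune
#' correlated features ([prune_correlated()]), remove outliers
#' ([remove_outliers()]) and fit the pruned logistic classifier
#' ([fit_risk_model()]). Every stage warning of class `liftrisk_warning`
#' (Nyquist clamps, envelope-frame shrinks, unmatched lift counts, constant
#' features) is harvested into the run manifest together with the full
#' parameter snapshot and seed, so a run can be reproduced exactly.
#'
#' @param config A [synth_config()] describing the cohort.
#' @param seed Master seed for the simulation.
#' @param segmentation Named list of overrides passed to
#'   [segment_recording()] (default uses the `"auto"` envelope frame and the
#'   configured lift count as `expected_count`).
#' @param alpha Significance level for screening and Wald pruning.
#' @param r_threshold Correlation-pruning threshold.
#' @param or_epsilon Odds-ratio-near-1 pruning threshold.
#' @param use_truth_rois Use the generator's ground-truth intervals instead
#'   of running the detector (for diagnosing the segmentation stage).
#' @return List of class `lift_pipeline`: `features`, `rois`, `screen`,
#'   `kept_features`, `outliers`, `model` and `manifest`.
#' @export
run_pipeline <- function(config = synth_config(), seed = 1,
                         segmentation = list(), alpha = 0.05,
                         r_threshold = 0.7, or_epsilon = 0.01,
                         use_truth_rois = FALSE) {
  warnings_log <- character(0)
  collect <- function(expr) {
    withCallingHandlers(expr, liftrisk_warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  cohort <- generate_cohort(config, seed)
  seg_args <- utils::modifyList(
    list(channel = "ax", sg_frame = "auto",
         lifts_per_min = config$lifts_per_min,
         expected_count = config$n_lifts),
    segmentation
  )
  rois <- if (use_truth_rois) {
    cohort$truth
  } else {
    collect(purrr::map_dfr(cohort$recordings, function(rec) {
      do.call(segment_recording, c(list(recording = rec), seg_args))
    }))
  }
  features <- build_feature_table(cohort$recordings, rois)
  screen <- collect(screen_features(features, alpha = alpha))
  kept <- collect(prune_correlated(features, r_threshold = r_threshold))
  out <- collect(remove_outliers(features, kept))
  model <- collect(fit_risk_model(out$table, kept, alpha = alpha,
                                  or_epsilon = or_epsilon))
  stopifnot(nrow(features) == nrow(out$table) + nrow(out$removed))
  manifest <- list(
    schema = "liftrisk-manifest-v1",
    seed = seed,
    config = unclass(config),
    segmentation = seg_args,
    alpha = alpha, r_threshold = r_threshold, or_epsilon = or_epsilon,
    n_instances = nrow(features),
    n_removed_outliers = nrow(out$removed),
    warnings = warnings_log
  )
  structure(list(
    features = features, rois = rois, screen = screen,
    kept_features = kept, outliers = out, model = model,
    manifest = manifest
  ), class = "lift_pipeline")
}

#' @export
print.lift_pipeline <- function(x, ...) {
  cat(sprintf("<lift_pipeline> %d lift instances, %d/%d features significant\n",
              nrow(x$features), sum(x$screen$significant), nrow(x$screen)))
  cat(sprintf("  correlation pruning kept %d features; %d outliers removed\n",
              length(x$kept_features), nrow(x$outliers$removed)))
  print(x$model)
  invisible(x)
}

#' Write a pipeline run to disk
#'
#' Persists the feature table, screening table, ROI table (CSV), model
#' report and manifest (JSON) under one directory.
#'
#' @param pipeline A `lift_pipeline` result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(pipeline, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(pipeline$features, file.path(dir, "features.csv"),
                   progress = FALSE)
  write_rois(pipeline$rois, file.path(dir, "rois.csv"))
  readr::write_csv(tibble::as_tibble(pipeline$screen),
                   file.path(dir, "screen.csv"), progress = FALSE)
  report <- list(
    final_features = pipeline$model$final_features,
    coefficients = pipeline$model$coefficients,
    events_per_variable = pipeline$model$events_per_variable,
    confusion = pipeline$model$confusion,
    accuracy = pipeline$model$accuracy,
    sensitivity = pipeline$model$sensitivity,
    specificity = pipeline$model$specificity,
    protocol = pipeline$model$protocol,
    removed_outliers = pipeline$outliers$removed
  )
  jsonlite::write_json(report, file.path(dir, "model_report.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(pipeline$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
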