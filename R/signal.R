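#' Construct a 6-channel inertial recording
#'
#' Wraps a tibble of sampled inertial data in a light recording container.
#' Channels follow the sternum-sensor convention: `ax`, `ay`, `az` are linear
#' accelerations (m/s^2) along the vertical (x), horizontal (y) and
#' sensor-normal (z) axes, and `vx`, `vy`, `vz` the matching angular
#' velocities (rad/s). The sampling rate is carried as metadata rather than
#' assumed, because the segmentation stage needs it for every time-based
#' parameter.
#'
#' @param data Data frame with columns `t, ax, ay, az, vx, vy, vz`; samples
#'   must be complete (any missing value is a load-time error).
#' @param fs Sampling rate in Hz (> 0).
#' @param subject_id Opaque subject identifier.
#' @param trial_label `"NO_RISK"`, `"RISK"` or `"unknown"`.
#' @return A tibble of class `lift_recording` with attributes `fs`,
#'   `subject_id` and `trial_label`.
#' @export
lift_recording <- function(data, fs, subject_id = "S", trial_label = "unknown") {
  fs <- check_number(fs, min = 0, strict_min = TRUE)
  trial_label <- check_enum(trial_label, c("NO_RISK", "RISK", "unknown"))
  need <- c("t", channel_names())
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("recording is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)[need]
  if (anyNA(data)) abort("recording contains missing samples (gaps)")
  structure(
    data,
    class = c("lift_recording", class(tibble::tibble())),
    fs = fs, subject_id = subject_id, trial_label = trial_label
  )
}

#' @export
print.lift_recording <- function(x, ...) {
  cat(sprintf("<lift_recording> subject %s, trial %s, fs %g Hz, %d samples (%.1f s)\n",
              attr(x, "subject_id"), attr(x, "trial_label"), attr(x, "fs"),
              nrow(x), nrow(x) / attr(x, "fs")))
  NextMethod()
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies an order-`order` Butterworth band-pass (default 1-50 Hz) in
#' forward-backward (zero-phase) form, so later envelope thresholding does not
#' inherit a phase shift. The upper cutoff is clamped to `0.45 * fs` when the
#' requested band extends past what the sampling rate supports (a 20 Hz
#' recording cannot carry a 50 Hz band edge); the clamp is signalled as a
#' warning of class `liftrisk_nyquist_clamp` so run manifests can record it.
#'
#' @param x Numeric series.
#' @param fs Sampling rate (Hz).
#' @param low_hz,high_hz Pass-band edges (Hz).
#' @param order Overall filter order (even; the band-pass is designed as
#'   `order/2` second-order sections worth of poles per edge).
#' @return Filtered series, same length, DC removed.
#' @export
bandpass_filter <- function(x, fs, low_hz = 1, high_hz = 50, order = 8) {
  fs <- check_number(fs, min = 0, strict_min = TRUE)
  eff_high <- min(high_hz, 0.45 * fs)
  if (eff_high <= low_hz) {
    abort(sprintf(
      "band-pass collapses: 0.45*fs = %.3g Hz is not above low_hz = %.3g Hz",
      0.45 * fs, low_hz))
  }
  if (eff_high < high_hz) {
    lift_warn(sprintf(
      "upper cutoff clamped from %g to %.3g Hz (Nyquist guard at fs = %g Hz)",
      high_hz, eff_high, fs), "liftrisk_nyquist_clamp")
  }
  bf <- signal::butter(max(1L, as.integer(order / 2)),
                       c(low_hz, eff_high) / (fs / 2), type = "pass")
  # remove the mean first: DC is outside the pass-band anyway, and a large
  # offset leaves edge transients through the forward-backward pass
  as.numeric(signal::filtfilt(bf, x - mean(x)))
}

#' Savitzky-Golay amplitude envelope
#'
#' Rectifies a (band-passed) series and smooths it with a Savitzky-Golay
#' filter (default polynomial order 3, frame length 1001 samples) to obtain
#' the amplitude envelope used for lift detection. Frames longer than the
#' series are shrunk to the largest valid odd length and signalled as a
#' warning of class `liftrisk_sg_shrink`.
#'
#' @param x Numeric series.
#' @param sg_order Polynomial order of the smoother.
#' @param sg_frame Odd frame length in samples.
#' @return Non-negative-biased envelope, same length as `x`.
#' @export
signal_envelope <- function(x, sg_order = 3, sg_frame = 1001) {
  if (length(x) < sg_order + 2) {
    abort(sprintf("series too short for envelope (need >= %d samples)", sg_order + 2))
  }
  sg_frame <- as.integer(sg_frame)
  if (sg_frame %% 2L == 0L) sg_frame <- sg_frame + 1L
  if (sg_frame > length(x)) {
    new_frame <- length(x) - (1 - length(x) %% 2L)
    lift_warn(sprintf("Savitzky-Golay frame shrunk from %d to %d samples",
                      sg_frame, new_frame), "liftrisk_sg_shrink")
    sg_frame <- as.integer(new_frame)
  }
  if (sg_frame <= sg_order) {
    abort("Savitzky-Golay frame must exceed the polynomial order")
  }
  # local-polynomial smoothing can overshoot below zero near sharp edges;
  # the envelope is defined as non-negative, so clip
  pmax(as.numeric(signal::sgolayfilt(abs(x), p = sg_order, n = sg_frame)), 0)
}

roi_runs <- function(env, fs, threshold, min_duration_s, min_gap_s) {
  above <- env >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  runs <- cbind(start = starts[keep] - 1L, end = ends[keep])  # 0-based, half-open
  if (nrow(runs) == 0) return(runs)
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      if ((runs[i, 1] - merged[nrow(merged), 2]) / fs < min_gap_s) {
        merged[nrow(merged), 2] <- runs[i, 2]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  merged[(merged[, 2] - merged[, 1]) / fs >= min_duration_s, , drop = FALSE]
}

#' Detect lift regions of interest on an amplitude envelope
#'
#' Thresholds the envelope at `theta = alpha * P95(envelope)` and returns the
#' maximal runs above threshold as half-open, 0-based sample intervals. Runs
#' separated by less than `min_gap_s` are merged, then runs shorter than
#' `min_duration_s` are discarded. When the number of lifts in the trial is
#' known, `expected_count` turns on a bisection search over
#' `alpha in [0.05, 0.95]` that stops when the run count matches; if no alpha
#' matches, the closest solution is returned with a warning of class
#' `liftrisk_alpha_unmatched`.
#'
#' @param env Non-negative envelope series.
#' @param fs Sampling rate (Hz).
#' @param alpha Relative threshold factor applied to the envelope's 95th
#'   percentile (default 0.3).
#' @param min_duration_s Minimum lift duration retained (s).
#' @param min_gap_s Runs closer than this are merged (s).
#' @param expected_count Optional known lift count to match.
#' @return Tibble with 0-based half-open `start`/`end` sample indices,
#'   `start_s`/`end_s` in seconds and the `alpha` actually used.
#' @export
detect_rois <- function(env, fs, alpha = 0.3, min_duration_s = 1,
                        min_gap_s = 2, expected_count = NULL) {
  if (any(env < 0)) abort("envelope must be non-negative")
  fs <- check_number(fs, min = 0, strict_min = TRUE)
  as_roi_tbl <- function(runs, a) {
    tibble::tibble(
      start = as.integer(unname(runs[, 1])), end = as.integer(unname(runs[, 2])),
      start_s = unname(runs[, 1]) / fs, end_s = unname(runs[, 2]) / fs,
      alpha = a
    )
  }
  if (max(env) == 0) {
    if (!is.null(expected_count) && expected_count > 0) {
      abort("flat-zero envelope: no lifts detectable but expected_count > 0")
    }
    return(as_roi_tbl(matrix(numeric(0), 0, 2), alpha))
  }
  scale <- quantile(env, 0.95, names = FALSE)
  if (scale <= 0) scale <- max(env)
  # contrast guard: a lift train has a quiet baseline most of the time, so
  # P95 sits well above the median; a flat (noise-only) envelope does not,
  # and a relative threshold would then select one giant run
  if (scale < 2 * stats::median(env)) {
    if (!is.null(expected_count) && expected_count > 0) {
      abort("envelope has no lift-like contrast (P95 < 2 * median) but expected_count > 0")
    }
    lift_warn("envelope has no lift-like contrast (P95 < 2 * median); no ROIs detected",
              "liftrisk_low_contrast")
    return(as_roi_tbl(matrix(numeric(0), 0, 2), alpha))
  }
  runs_at <- function(a) roi_runs(env, fs, a * scale, min_duration_s, min_gap_s)
  if (is.null(expected_count)) {
    return(as_roi_tbl(runs_at(alpha), alpha))
  }
  # bisection on alpha until the run count matches expected_count
  lo <- 0.05; hi <- 0.95
  best <- NULL; best_diff <- Inf
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    runs <- runs_at(mid)
    d <- nrow(runs) - expected_count
    if (abs(d) < best_diff) {
      best <- list(runs = runs, alpha = mid); best_diff <- abs(d)
    }
    if (d == 0) break
    if (d > 0) lo <- mid else hi <- mid  # too many runs -> raise threshold
  }
  if (best_diff != 0) {
    lift_warn(sprintf(
      "could not match expected_count = %d lifts (closest: %d at alpha = %.3f)",
      expected_count, expected_count + as.integer(best_diff), best$alpha),
      "liftrisk_alpha_unmatched")
  }
  as_roi_tbl(best$runs, best$alpha)
}

#' Segment a recording into per-lift regions of interest
#'
#' Runs the full detection chain on one reference channel of a recording:
#' band-pass filter, rectification, Savitzky-Golay envelope and envelope
#' thresholding ([detect_rois()]). The resulting sample intervals apply to all
#' six channels. `sg_frame = "auto"` sets the envelope frame to the nearest
#' odd number of samples to `0.4 * fs * (60 / lifts_per_min)`, i.e. 40% of
#' the nominal lift period, which keeps the envelope matched to the lift
#' timescale at any sampling rate; the numeric default honours the classic
#' 1001-sample frame.
#'
#' @param recording A [lift_recording()].
#' @param channel Reference channel for detection (default `"ax"`, the
#'   vertical acceleration).
#' @param low_hz,high_hz,order Band-pass settings (see [bandpass_filter()]).
#' @param sg_order,sg_frame Envelope settings; `sg_frame` may be `"auto"`.
#' @param alpha,min_duration_s,min_gap_s,expected_count Threshold policy
#'   (see [detect_rois()]).
#' @param lifts_per_min Nominal lift rate used by the `"auto"` frame rule.
#' @return Tibble of regions of interest with recording identifiers attached.
#' @export
segment_recording <- function(recording, channel = "ax",
                              low_hz = 1, high_hz = 50, order = 8,
                              sg_order = 3, sg_frame = 1001,
                              alpha = 0.3, min_duration_s = 1, min_gap_s = 2,
                              expected_count = NULL, lifts_per_min = 4) {
  stopifnot(inherits(recording, "lift_recording"))
  channel <- check_enum(channel, channel_names())
  fs <- attr(recording, "fs")
  if (identical(sg_frame, "auto")) {
    sg_frame <- 2 * floor(0.4 * fs * (60 / lifts_per_min) / 2) + 1
  }
  filtered <- bandpass_filter(recording[[channel]], fs,
                              low_hz = low_hz, high_hz = high_hz, order = order)
  env <- signal_envelope(filtered, sg_order = sg_order, sg_frame = sg_frame)
  rois <- detect_rois(env, fs, alpha = alpha, min_duration_s = min_duration_s,
                      min_gap_s = min_gap_s, expected_count = expected_count)
  tibble::tibble(
    subject = attr(recording, "subject_id"),
    trial = attr(recording, "trial_label"),
    lift_index = seq_len(nrow(rois)),
    rois[c("start", "end", "start_s", "end_s", "alpha")],
    source_channel = channel
  )
}
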