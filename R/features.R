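#' The 19-entry feature catalogue
#'
#' Eleven time-domain descriptors (RSA, PPA, MEAN, SD, HM, 25P, 75P, ZC, CL,
#' FD, NSC) and eight frequency-domain descriptors (EN, KU, SK, POW, MDF,
#' MNF, PPS, PF) computed per lift and per channel. Applied to the six
#' inertial channels this yields the 19 x 2 signals x 3 axes = 114 feature
#' columns of the analysis table; column names are the feature name followed
#' by the channel suffix (e.g. `RSAax`, `MDFvz`).
#'
#' @return Tibble with columns `feature`, `domain` and `description`.
#' @export
feature_catalog <- function() {
  tibble::tibble(
    feature = c("RSA", "PPA", "MEAN", "SD", "HM", "25P", "75P", "ZC", "CL",
                "FD", "NSC",
                "EN", "KU", "SK", "POW", "MDF", "MNF", "PPS", "PF"),
    domain = c(rep("time", 11), rep("frequency", 8)),
    description = c(
      "rectified signal area (sum |x| * dt)",
      "peak-to-peak amplitude",
      "mean of the rectified segment",
      "standard deviation (signed segment)",
      "harmonic mean (signed; near-zero samples excluded)",
      "25th percentile (signed segment)",
      "75th percentile (signed segment)",
      "zero crossings (strict sign changes)",
      "cumulative length (sum |diff(x)|)",
      "Katz waveform fractal dimension",
      "number of slope changes (sign changes of first differences)",
      "normalised spectral entropy",
      "kurtosis of the power-spectrum values",
      "skewness of the power-spectrum values",
      "total spectral power",
      "median frequency (50% cumulative power)",
      "mean (power-weighted) frequency",
      "peak of the power spectrum",
      "peak frequency (lowest on ties)"
    )
  )
}

# strict sign changes, ignoring exact zeros
count_sign_changes <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(s[-1] != s[-length(s)])
}

katz_fd <- function(x) {
  n <- length(x) - 1
  if (n < 1) return(1.0)
  dx <- diff(x)
  # planar sample-index curve: unit abscissa step per sample
  L <- sum(sqrt(1 + dx^2))
  d <- max(sqrt((seq_along(x) - 1)^2 + (x - x[1])^2))
  if (L <= 0 || d <= 0) return(1.0)
  log10(n) / (log10(n) + log10(d / L))
}

#' Time-domain features of one lift segment
#'
#' @param x Numeric segment (one channel, one lift), length >= 8.
#' @param fs Sampling rate (Hz).
#' @param roi_id Optional identifier used in error messages.
#' @return Named list of the 11 time-domain feature values: `RSA` (integral
#'   of the rectified signal), `PPA`, `MEAN` (of the rectified segment; the
#'   signed band-passed mean is ~0 by construction), `SD`, `HM` (harmonic
#'   mean of the signed segment with samples below 1e-12 in magnitude
#'   excluded -- numerically explosive on zero-crossing signals, and reported
#'   as-is), `25P`, `75P`, `ZC`, `CL`, `FD` (Katz, >= 1, equal to 1 for a
#'   degenerate flat segment) and `NSC`.
#' @export
time_features <- function(x, fs, roi_id = NULL) {
  if (length(x) < 8) {
    abort(sprintf("segment%s too short for time features (%d < 8 samples)",
                  if (is.null(roi_id)) "" else paste0(" ", roi_id), length(x)))
  }
  dx <- diff(x)
  nz <- x[abs(x) >= 1e-12]
  hm <- if (length(nz)) length(nz) / sum(1 / nz) else 0
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  list(
    RSA = sum(abs(x)) / fs,
    PPA = max(x) - min(x),
    MEAN = mean(abs(x)),
    SD = sd(x),
    HM = hm,
    `25P` = q[1],
    `75P` = q[2],
    ZC = count_sign_changes(x),
    CL = sum(abs(dx)),
    FD = katz_fd(x),
    NSC = count_sign_changes(dx)
  )
}

#' One-sided power spectrum of a segment
#'
#' Raw (unwindowed) FFT periodogram with the DC bin excluded:
#' `P_k = |X_k|^2 / N^2` at `f_k = k fs / N`, `k = 1..floor(N/2)`.
#'
#' @param x Numeric segment.
#' @param fs Sampling rate (Hz).
#' @return Tibble with columns `freq` and `power`.
#' @export
power_spectrum <- function(x, fs) {
  n <- length(x)
  X <- fft(x)
  k <- seq_len(floor(n / 2))
  tibble::tibble(freq = k * fs / n, power = Mod(X[k + 1])^2 / n^2)
}

spectrum_moments <- function(p) {
  m <- mean(p); s2 <- mean((p - m)^2)
  if (s2 <= 0) return(c(KU = 0, SK = 0))
  c(KU = mean((p - m)^4) / s2^2, SK = mean((p - m)^3) / s2^1.5)
}

# frequency-domain features from an explicit spectrum (freq, power);
# exposed separately so degenerate/synthetic spectra can be injected directly
spectral_features <- function(freq, power) {
  POW <- sum(power)
  if (POW <= 0 || length(power) < 2) {
    return(list(EN = 0, KU = 0, SK = 0, POW = 0, MDF = 0, MNF = 0,
                PPS = 0, PF = 0))
  }
  p <- power / POW
  nzp <- p[p > 0]
  EN <- if (length(nzp) <= 1) 0 else -sum(nzp * log(nzp)) / log(length(p))
  ms <- spectrum_moments(power)
  cum <- cumsum(power)
  MDF <- freq[which(cum >= 0.5 * POW)[1]]
  MNF <- sum(freq * power) / POW
  imax <- which.max(power)  # which.max returns the first (lowest-f) maximum
  list(EN = EN, KU = unname(ms["KU"]), SK = unname(ms["SK"]), POW = POW,
       MDF = MDF, MNF = MNF, PPS = power[imax], PF = freq[imax])
}

#' Frequency-domain features of one lift segment
#'
#' Computes the eight spectral descriptors from the one-sided FFT power
#' spectrum (DC excluded): normalised spectral entropy `EN` in `[0, 1]`
#' (0 for a one-bin spectrum, 1 for a uniform one), kurtosis `KU` and
#' skewness `SK` of the spectrum-value distribution, total power `POW`,
#' median frequency `MDF` (lowest frequency reaching 50% cumulative power),
#' power-weighted mean frequency `MNF`, spectrum peak `PPS` and peak
#' frequency `PF` (lowest frequency on ties). An all-zero segment yields the
#' documented degenerate values (all zero).
#'
#' @param x Numeric segment, length >= 16.
#' @param fs Sampling rate (Hz).
#' @param roi_id Optional identifier used in error messages.
#' @return Named list of the 8 frequency-domain feature values.
#' @export
freq_features <- function(x, fs, roi_id = NULL) {
  if (length(x) < 16) {
    abort(sprintf("segment%s too short for frequency features (%d < 16 samples)",
                  if (is.null(roi_id)) "" else paste0(" ", roi_id), length(x)))
  }
  ps <- power_spectrum(x, fs)
  spectral_features(ps$freq, ps$power)
}

#' Assemble the 114-column feature table
#'
#' Extracts all 19 features from all six channels for every region of
#' interest, yielding one row per lift with identifier columns
#' (`subject`, `trial`, `lift_index`), the class `label` and 114 feature
#' columns named feature-then-channel (`RSAax` ... `PFvz`), grouped by
#' channel in catalogue order.
#'
#' @param recordings A list of [lift_recording()] objects (or a single one).
#' @param rois Tibble of regions of interest as produced by
#'   [segment_recording()]; rows are matched to recordings by
#'   `(subject, trial)`.
#' @return Tibble with `4 + 114` columns and one row per ROI.
#' @export
build_feature_table <- function(recordings, rois) {
  if (inherits(recordings, "lift_recording")) recordings <- list(recordings)
  keys <- vapply(recordings, function(r) {
    paste(attr(r, "subject_id"), attr(r, "trial_label"), sep = "\r")
  }, character(1))
  feature_cols <- as.vector(t(outer(channel_names(), feature_catalog()$feature,
                                    function(ch, f) paste0(f, ch))))
  if (nrow(rois) == 0) {
    out <- matrix(numeric(0), 0, length(feature_cols),
                  dimnames = list(NULL, feature_cols))
    return(dplyr::bind_cols(
      tibble::tibble(subject = character(0), trial = character(0),
                     lift_index = integer(0), label = character(0)),
      tibble::as_tibble(out)
    ))
  }
  rows <- purrr::pmap(rois[c("subject", "trial", "lift_index", "start", "end")],
    function(subject, trial, lift_index, start, end) {
      m <- match(paste(subject, trial, sep = "\r"), keys)
      if (is.na(m)) {
        abort(sprintf("no recording found for subject %s, trial %s", subject, trial))
      }
      rec <- recordings[[m]]
      fs <- attr(rec, "fs")
      if (start < 0 || end > nrow(rec) || start >= end) {
        abort(sprintf("ROI [%d, %d) out of bounds for subject %s, trial %s",
                      start, end, subject, trial))
      }
      idx <- (start + 1):end
      vals <- unlist(lapply(channel_names(), function(ch) {
        seg <- rec[[ch]][idx]
        id <- sprintf("%s/%s/lift %d/%s", subject, trial, lift_index, ch)
        c(unlist(time_features(seg, fs, roi_id = id)),
          unlist(freq_features(seg, fs, roi_id = id)))
      }))
      names(vals) <- feature_cols
      vals
    })
  dplyr::bind_cols(
    tibble::tibble(subject = rois$subject, trial = rois$trial,
                   lift_index = rois$lift_index,
                   label = rois$trial),
    tibble::as_tibble(do.call(rbind, rows))
  )
}

#' Names of the 114 feature columns in catalogue order
#' @return Character vector of length 114 (channel-major, catalogue order).
#' @export
feature_column_names <- function() {
  as.vector(t(outer(channel_names(), feature_catalog()$feature,
                    function(ch, f) paste0(f, ch))))
}
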