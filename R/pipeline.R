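#' Filter specification for the processing pipeline
#'
#' @param lowpass_cutoff Low-pass corner frequency (Hz). Default 10 Hz:
#'   preserves arterial pulse morphology (fundamental ~1-3 Hz plus a few
#'   harmonics) while attenuating movement noise.
#' @param filter_order Butterworth order (>= 1); default 4.
#' @param reference_smoothing_window Moving-average window (s) applied to the
#'   reference channel before subtraction. Default 1.0 s: suppresses any
#'   pulse leakage into the reference while tracking baseline drift.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(lowpass_cutoff = 10, filter_order = 4,
                        reference_smoothing_window = 1.0) {
  stop_if_not_scalar(lowpass_cutoff, "lowpass_cutoff", positive = TRUE)
  stop_if_not_scalar(filter_order, "filter_order", positive = TRUE)
  if (filter_order != round(filter_order)) {
    stop("`filter_order` must be a whole number", call. = FALSE)
  }
  stop_if_not_scalar(reference_smoothing_window, "reference_smoothing_window",
                     positive = TRUE)
  structure(
    list(lowpass_cutoff = lowpass_cutoff,
         filter_order = as.integer(filter_order),
         reference_smoothing_window = reference_smoothing_window),
    class = "filter_spec"
  )
}

#' Zero-phase low-pass filter
#'
#' Butterworth low-pass applied forward and backward (zero phase lag, so beat
#' timing is preserved), with reflection padding at both ends to suppress
#' edge transients. DC gain is unity and output length equals input length.
#'
#' @param series Pressure series (mmHg).
#' @param sample_rate Sampling rate (Hz).
#' @param spec A [filter_spec()].
#' @return Filtered series, same length.
#' @export
lowpass_filter <- function(series, sample_rate, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  stop_if_not_scalar(sample_rate, "sample_rate", positive = TRUE)
  if (spec$lowpass_cutoff >= sample_rate / 2) {
    stop("low-pass cutoff must be below the Nyquist frequency", call. = FALSE)
  }
  n <- length(series)
  if (n <= 3 * spec$filter_order) {
    stop("series too short for the requested filter order", call. = FALSE)
  }
  bf <- signal::butter(spec$filter_order,
                       spec$lowpass_cutoff / (sample_rate / 2), type = "low")
  # pad long enough for the filter's zero-state transient to decay below
  # numerical noise before the retained segment begins
  pad <- min(n - 1, max(10L * ceiling(sample_rate / spec$lowpass_cutoff),
                        50L * spec$filter_order))
  # odd (point-reflected) extension keeps both value and slope continuous
  left <- 2 * series[1] - series[seq(pad + 1, 2)]
  right <- 2 * series[n] - series[seq(n - 1, n - pad)]
  ext <- c(left, series, right)
  out <- signal::filtfilt(bf, ext)
  out[(pad + 1):(pad + n)]
}

#' Smooth the reference channel with a centered moving average
#'
#' Centered moving average whose window shrinks symmetrically near the ends
#' of the series (so constants and linear ramps pass unchanged everywhere).
#'
#' @param series Pressure series (mmHg).
#' @param sample_rate Sampling rate (Hz).
#' @param window Window length (s); must span at least 2 samples and not
#'   exceed the series.
#' @return Smoothed series, same length.
#' @export
smooth_reference <- function(series, sample_rate, window = 1.0) {
  stop_if_not_scalar(sample_rate, "sample_rate", positive = TRUE)
  stop_if_not_scalar(window, "window", positive = TRUE)
  n <- length(series)
  w <- round(window * sample_rate)
  if (w < 2) stop("smoothing window must span at least 2 samples", call. = FALSE)
  if (w > n) stop("smoothing window longer than the series", call. = FALSE)
  k <- w %/% 2
  cs <- cumsum(c(0, series))
  i <- seq_len(n)
  ki <- pmin(k, i - 1L, n - i)
  (cs[i + ki + 1] - cs[i - ki]) / (2 * ki + 1)
}

#' Isolate the arterial waveform from the two channels
#'
#' Subtracts the (smoothed) reference contact-pressure signal from the
#' primary signal and undoes the tissue attenuation:
#' \deqn{P_a(t) = (P_{measured,1} - P_{measured,2}) e^{\alpha}}
#'
#' @param primary Primary-channel series (mmHg).
#' @param smoothed_reference Smoothed reference-channel series, same length.
#' @param alpha Attenuation coefficient (>= 0) used for un-attenuation.
#' @return Arterial pressure series (mmHg).
#' @export
isolate_arterial <- function(primary, smoothed_reference, alpha) {
  if (length(primary) != length(smoothed_reference)) {
    stop("primary and reference series must have equal length", call. = FALSE)
  }
  stop_if_not_scalar(alpha, "alpha", nonnegative = TRUE)
  (primary - smoothed_reference) * exp(alpha)
}

# Prominence of the local maximum at index i: height above the higher of the
# two valley floors separating it from taller terrain (or the series ends).
peak_prominence <- function(x, peaks) {
  n <- length(x)
  vapply(peaks, function(i) {
    h <- x[i]
    j <- i
    left_min <- h
    while (j > 1 && x[j - 1] <= h) {
      j <- j - 1
      if (x[j] < left_min) left_min <- x[j]
    }
    j <- i
    right_min <- h
    while (j < n && x[j + 1] <= h) {
      j <- j + 1
      if (x[j] < right_min) right_min <- x[j]
    }
    h - max(left_min, right_min)
  }, numeric(1))
}

#' Detect cardiac beats in an arterial pressure series
#'
#' Prominence-based systolic peak picking with a refractory interval, then
#' per-beat diastolic foot location as the minimum over the preceding
#' inter-peak interval. Designed for heart rates of roughly 40-180 bpm.
#'
#' @param arterial Arterial pressure series (mmHg), baseline-free or nearly so.
#' @param sample_rate Sampling rate (Hz).
#' @param refractory Minimum spacing between successive peaks (s); default
#'   0.33 s (180 bpm ceiling).
#' @param prominence_frac Prominence floor as a fraction of the robust signal
#'   amplitude (1st-99th percentile range); default 0.3.
#' @param min_prominence Absolute prominence floor (mmHg); default 1 mmHg in
#'   arterial units — a waveform whose peak rises less than 1 mmHg above its
#'   surroundings is not a credible cardiac beat, so residual noise in a
#'   pulseless series is not mistaken for one.
#' @return A `beat_series`: data frame-like list with `beat_times` (s, peak
#'   times, strictly increasing), `peak_values`, `foot_values` and
#'   `ac_amplitudes` (peak minus foot, mmHg). Zero beats (with a warning)
#'   when no peak clears the prominence floor.
#' @export
detect_beats <- function(arterial, sample_rate, refractory = 0.33,
                         prominence_frac = 0.3, min_prominence = 1) {
  stop_if_not_scalar(sample_rate, "sample_rate", positive = TRUE)
  n <- length(arterial)
  empty <- structure(
    list(beat_times = numeric(0), peak_values = numeric(0),
         foot_values = numeric(0), ac_amplitudes = numeric(0)),
    class = "beat_series"
  )
  if (n < 3) {
    warning("series too short for beat detection; returning no beats")
    return(empty)
  }
  x <- as.numeric(arterial)
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(cand) == 0) {
    warning("no oscillation found; returning no beats")
    return(empty)
  }
  rng <- unname(diff(stats::quantile(x, c(0.01, 0.99))))
  floor_p <- max(min_prominence, prominence_frac * rng)
  prom <- peak_prominence(x, cand)
  keep <- cand[prom >= floor_p]
  if (length(keep) == 0) {
    warning("no peaks above the prominence floor; returning no beats")
    return(empty)
  }
  # enforce refractory interval, keeping the taller of two close peaks
  min_gap <- round(refractory * sample_rate)
  ord <- keep[order(x[keep], decreasing = TRUE)]
  accepted <- integer(0)
  for (i in ord) {
    if (all(abs(accepted - i) >= min_gap)) accepted <- c(accepted, i)
  }
  peaks <- sort(accepted)
  # foot: minimum over the preceding inter-peak interval (bounded lookback
  # of 1.5 s for the first beat)
  max_back <- as.integer(round(1.5 * sample_rate))
  feet <- vapply(seq_along(peaks), function(k) {
    lo <- if (k == 1) max(1L, peaks[1] - max_back) else peaks[k - 1]
    as.integer(lo + which.min(x[lo:peaks[k]]) - 1L)
  }, integer(1))
  pv <- x[peaks]
  fv <- x[feet]
  ok <- pv > fv
  if (!all(ok)) {
    peaks <- peaks[ok]; feet <- feet[ok]; pv <- pv[ok]; fv <- fv[ok]
  }
  structure(
    list(beat_times = (peaks - 1) / sample_rate,
         peak_values = pv, foot_values = fv, ac_amplitudes = pv - fv),
    class = "beat_series"
  )
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("Beat series: %d beats", length(x$beat_times)))
  if (length(x$beat_times) > 1) {
    hr <- 60 / mean(diff(x$beat_times))
    cat(sprintf(", mean HR %.1f bpm, mean AC amplitude %.3g mmHg",
                hr, mean(x$ac_amplitudes)))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.beat_series <- function(x) length(x$beat_times)

#' @export
as.data.frame.beat_series <- function(x, ...) {
  data.frame(beat_time_s = x$beat_times, peak_mmHg = x$peak_values,
             foot_mmHg = x$foot_values, ac_amplitude_mmHg = x$ac_amplitudes)
}

#' Fit the beat-to-BP calibration maps
#'
#' Least-squares affine maps from detected peak values to reference systolic
#' pressure and from foot values to reference diastolic pressure, over a
#' calibration segment where the device ran alongside a beat-to-beat
#' reference monitor. With fewer than two distinct peak (or foot) values the
#' affine fit is rank-deficient and an offset-only map with unit gain is
#' used instead.
#'
#' @param beats A `beat_series` from [detect_beats()].
#' @param reference_sbp,reference_dbp Reference SBP/DBP values (mmHg), one
#'   per beat (already time-aligned; see [pair_nearest()]).
#' @return A `bp_calibration_map` with `systolic` and `diastolic` components,
#'   each `(gain, offset)`.
#' @export
fit_bp_calibration <- function(beats, reference_sbp, reference_dbp) {
  stopifnot(inherits(beats, "beat_series"))
  nb <- length(beats$beat_times)
  if (nb == 0 || length(reference_sbp) != nb || length(reference_dbp) != nb) {
    stop("reference values must match the beat series after alignment",
         call. = FALSE)
  }
  affine_map <- function(x, y) {
    if (length(unique(round(x, 12))) < 2) {
      list(gain = 1, offset = mean(y - x))
    } else {
      cf <- stats::coef(stats::lm(y ~ x))
      list(gain = unname(cf[2]), offset = unname(cf[1]))
    }
  }
  structure(
    list(systolic = affine_map(beats$peak_values, reference_sbp),
         diastolic = affine_map(beats$foot_values, reference_dbp),
         n_calibration_beats = nb),
    class = "bp_calibration_map"
  )
}

#' Identity BP calibration map
#'
#' Unit gain, zero offset for both maps: useful when the isolated arterial
#' waveform is already in absolute mmHg (e.g. simulation round trips).
#' @return A `bp_calibration_map`.
#' @export
identity_bp_map <- function() {
  structure(
    list(systolic = list(gain = 1, offset = 0),
         diastolic = list(gain = 1, offset = 0),
         n_calibration_beats = 0L),
    class = "bp_calibration_map"
  )
}

#' Estimate beat-by-beat blood pressure from a dual-channel recording
#'
#' Runs the full chain: low-pass filter both channels, smooth the reference,
#' subtract and un-attenuate ([isolate_arterial()]), detect beats, and map
#' peaks/feet to SBP/DBP through the calibration map. Beats whose estimates
#' fall outside physiological bounds (SBP 60-260, DBP 30-150 mmHg) or where
#' SBP fails to exceed DBP are flagged, never silently dropped.
#'
#' @param recording A `dual_channel_recording`.
#' @param spec A [filter_spec()].
#' @param alpha Attenuation coefficient for un-attenuation (typically
#'   [predict_alpha()] at the recording's contact pressure).
#' @param map A `bp_calibration_map`.
#' @param ... Passed to [detect_beats()].
#' @return A `bp_estimate`: data frame with `beat_time_s`, `sbp_mmHg`,
#'   `dbp_mmHg` and `flag` (`"ok"`, `"out_of_range"` or `"sbp_le_dbp"`).
#' @export
estimate_bp <- function(recording, spec = filter_spec(), alpha, map, ...) {
  stopifnot(inherits(recording, "dual_channel_recording"),
            inherits(map, "bp_calibration_map"))
  fs <- recording$sample_rate
  run_stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", label, conditionMessage(e)), call. = FALSE)
    })
  }
  p <- run_stage("lowpass", lowpass_filter(recording$primary, fs, spec))
  r <- run_stage("lowpass", lowpass_filter(recording$reference, fs, spec))
  rs <- run_stage("smooth",
                  smooth_reference(r, fs, spec$reference_smoothing_window))
  arterial <- run_stage("isolate", isolate_arterial(p, rs, alpha))
  beats <- run_stage("detect", detect_beats(arterial, fs, ...))

  sbp <- map$systolic$gain * beats$peak_values + map$systolic$offset
  dbp <- map$diastolic$gain * beats$foot_values + map$diastolic$offset
  flag <- rep("ok", length(sbp))
  flag[sbp < 60 | sbp > 260 | dbp < 30 | dbp > 150] <- "out_of_range"
  flag[sbp <= dbp] <- "sbp_le_dbp"
  out <- data.frame(beat_time_s = beats$beat_times, sbp_mmHg = sbp,
                    dbp_mmHg = dbp, flag = flag,
                    stringsAsFactors = FALSE)
  structure(list(beats = out, alpha = alpha, n_beats = nrow(out)),
            class = "bp_estimate")
}

#' @export
print.bp_estimate <- function(x, ...) {
  cat(sprintf("BP estimate: %d beats (alpha = %.3g)\n", x$n_beats, x$alpha))
  if (x$n_beats > 0) {
    cat(sprintf("  SBP %.1f +/- %.1f mmHg, DBP %.1f +/- %.1f mmHg, %d flagged\n",
                mean(x$beats$sbp_mmHg), stats::sd(x$beats$sbp_mmHg),
                mean(x$beats$dbp_mmHg), stats::sd(x$beats$dbp_mmHg),
                sum(x$beats$flag != "ok")))
  }
  invisible(x)
}

#' @export
as.data.frame.bp_estimate <- function(x, ...) x$beats

#' Estimate the time lag between two synchronized series
#'
#' Cross-correlation lag alignment, emulating the protocol's synchronization
#' tap between the device and the reference monitor. A manual override wins
#' when supplied.
#'
#' @param device,reference Equal-rate series to align.
#' @param sample_rate Sampling rate (Hz).
#' @param max_lag Largest lag searched (s); default 5.
#' @param manual_lag Optional manual override (s); returned unchanged.
#' @return Lag in seconds by which `device` leads `reference`.
#' @export
estimate_lag <- function(device, reference, sample_rate, max_lag = 5,
                         manual_lag = NULL) {
  if (!is.null(manual_lag)) return(manual_lag)
  stop_if_not_scalar(sample_rate, "sample_rate", positive = TRUE)
  L <- min(round(max_lag * sample_rate), length(device) - 1)
  cc <- stats::ccf(device - mean(device), reference - mean(reference),
                   lag.max = L, plot = FALSE)
  cc$lag[which.max(cc$acf)] / sample_rate
}

#' Pair device beats with reference beats by nearest time
#'
#' Greedy nearest-neighbour pairing of beat times within a tolerance;
#' unmatched beats on either side are dropped from the pairing (their indices
#' are reported so nothing vanishes silently).
#'
#' @param device_times,reference_times Beat times (s).
#' @param max_dt Largest admissible pairing gap (s); default 0.5.
#' @return Data frame with `device_idx`, `reference_idx`, `dt`.
#' @export
pair_nearest <- function(device_times, reference_times, max_dt = 0.5) {
  if (length(device_times) == 0 || length(reference_times) == 0) {
    return(data.frame(device_idx = integer(0), reference_idx = integer(0),
                      dt = numeric(0)))
  }
  used <- rep(FALSE, length(reference_times))
  di <- integer(0); ri <- integer(0); dt <- numeric(0)
  for (i in seq_along(device_times)) {
    d <- abs(reference_times - device_times[i])
    d[used] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= max_dt) {
      used[j] <- TRUE
      di <- c(di, i); ri <- c(ri, j); dt <- c(dt, device_times[i] - reference_times[j])
    }
  }
  data.frame(device_idx = di, reference_idx = ri, dt = dt)
}
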