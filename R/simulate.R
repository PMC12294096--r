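#' Harmonic arterial pulse model
#'
#' Represents the arterial pressure waveform as a mean pressure plus a sum of
#' sinusoidal harmonics of the heart's contraction:
#' \deqn{P_a(t) = P_{mean} + \sum_{n=1}^{N} A_n \sin(2\pi f_n t + \phi_n)}
#'
#' @param mean_pressure Mean arterial pressure (mmHg).
#' @param harmonics Data frame with columns `amplitude` (mmHg, >= 0),
#'   `frequency` (Hz, strictly positive and strictly increasing) and `phase`
#'   (radians). May have zero rows for a constant (pulseless) signal.
#' @return An object of class `pulse_wave_model`.
#' @examples
#' m <- pulse_wave_model(93)                       # constant 93 mmHg
#' m <- pulse_wave_model(100, data.frame(
#'   amplitude = c(20, 8), frequency = c(1.2, 2.4), phase = c(0, 0)))
#' @export
pulse_wave_model <- function(mean_pressure,
                             harmonics = data.frame(amplitude = numeric(0),
                                                    frequency = numeric(0),
                                                    phase = numeric(0))) {
  stop_if_not_scalar(mean_pressure, "mean_pressure")
  harmonics <- as.data.frame(harmonics)
  needed <- c("amplitude", "frequency", "phase")
  if (!all(needed %in% names(harmonics))) {
    stop("`harmonics` needs columns amplitude, frequency, phase", call. = FALSE)
  }
  harmonics <- harmonics[needed]
  if (nrow(harmonics) > 0) {
    if (any(harmonics$amplitude < 0)) {
      stop("harmonic amplitudes must be >= 0", call. = FALSE)
    }
    if (any(harmonics$frequency <= 0)) {
      stop("harmonic frequencies must be strictly positive", call. = FALSE)
    }
    if (is.unsorted(harmonics$frequency, strictly = TRUE)) {
      stop("harmonic frequencies must be strictly increasing", call. = FALSE)
    }
  }
  structure(
    list(mean_pressure = mean_pressure, harmonics = harmonics,
         n_harmonics = nrow(harmonics)),
    class = "pulse_wave_model"
  )
}

#' @export
print.pulse_wave_model <- function(x, ...) {
  cat(sprintf("Pulse wave model: mean %.1f mmHg, %d harmonic(s)\n",
              x$mean_pressure, x$n_harmonics))
  if (x$n_harmonics > 0) print(x$harmonics)
  invisible(x)
}

#' Tissue model housing the attenuation coefficient
#'
#' Holds the lumped dimensionless attenuation coefficient `alpha` governing
#' the exponential loss of arterial pressure through the overlying tissue,
#' plus optional mechanical properties used only for qualitative impedance
#' exploration (see [mechanical_impedance()]).
#'
#' @param alpha Dimensionless attenuation coefficient, >= 0. The effective
#'   tissue depth is lumped into `alpha`, so the exponent is `alpha` itself.
#' @param elastic_modulus Tissue elastic modulus E (Pa), optional.
#' @param density Tissue density rho (kg/m^3), optional.
#' @param sound_speed Speed of sound through tissue c (m/s), optional.
#' @param effective_depth Effective tissue thickness d (m), optional.
#' @return An object of class `tissue_model`.
#' @export
tissue_model <- function(alpha, elastic_modulus = NULL, density = NULL,
                         sound_speed = NULL, effective_depth = NULL) {
  stop_if_not_scalar(alpha, "alpha", nonnegative = TRUE)
  for (nm in c("elastic_modulus", "density", "sound_speed", "effective_depth")) {
    v <- get(nm)
    if (!is.null(v)) stop_if_not_scalar(v, nm, positive = TRUE)
  }
  structure(
    list(alpha = alpha, elastic_modulus = elastic_modulus, density = density,
         sound_speed = sound_speed, effective_depth = effective_depth),
    class = "tissue_model"
  )
}

#' Contact-pressure profile for the worn sensor
#'
#' Describes the static and slowly varying pressure the strap-mounted sensor
#' exerts on the skin: a baseline, a deterministic drift, band-limited
#' Gaussian contact noise, optional motion artifacts, and a small independent
#' per-channel instrument-noise term. Baseline, drift, contact noise and
#' motion are shared by the two transducers (they ride the same chassis and
#' strap); only the instrument noise is drawn independently per channel.
#'
#' @param baseline Static contact pressure (mmHg, >= 0).
#' @param drift Either a function of time (seconds) returning mmHg, or a
#'   scalar linear drift rate in mmHg/s. Default: no drift.
#' @param noise_sd Standard deviation of the shared contact-pressure noise
#'   (mmHg, >= 0).
#' @param noise_bandwidth Bandwidth (Hz) of the contact noise; fluctuations in
#'   strap tension and tissue deformation are slow (respiration, posture), so
#'   the default is 0.3 Hz. Use `Inf` for white noise.
#' @param motion_events Data frame with columns `onset` (s), `duration` (s)
#'   and `amplitude` (mmHg); each event is a raised-cosine pressure bump.
#' @param instrument_noise_sd Standard deviation of the independent white
#'   sensor noise per channel (mmHg). Default 0.005 mmHg, consistent with a
#'   device able to resolve sub-millimetre-of-mercury waveform features.
#' @return An object of class `contact_pressure_profile`.
#' @export
contact_pressure_profile <- function(baseline,
                                     drift = NULL,
                                     noise_sd = 0,
                                     noise_bandwidth = 0.3,
                                     motion_events = NULL,
                                     instrument_noise_sd = 0.005) {
  stop_if_not_scalar(baseline, "baseline", nonnegative = TRUE)
  stop_if_not_scalar(noise_sd, "noise_sd", nonnegative = TRUE)
  stop_if_not_scalar(noise_bandwidth, "noise_bandwidth", positive = TRUE,
                     finite = FALSE)
  stop_if_not_scalar(instrument_noise_sd, "instrument_noise_sd",
                     nonnegative = TRUE)
  if (is.null(drift)) {
    drift_fun <- function(t) rep(0, length(t))
  } else if (is.function(drift)) {
    drift_fun <- drift
  } else {
    stop_if_not_scalar(drift, "drift")
    rate <- drift
    drift_fun <- function(t) rate * t
  }
  if (!is.null(motion_events)) {
    motion_events <- as.data.frame(motion_events)
    if (!all(c("onset", "duration", "amplitude") %in% names(motion_events))) {
      stop("`motion_events` needs columns onset, duration, amplitude",
           call. = FALSE)
    }
    if (any(motion_events$duration <= 0)) {
      stop("motion event durations must be positive", call. = FALSE)
    }
  }
  structure(
    list(baseline = baseline, drift = drift_fun, noise_sd = noise_sd,
         noise_bandwidth = noise_bandwidth, motion_events = motion_events,
         instrument_noise_sd = instrument_noise_sd),
    class = "contact_pressure_profile"
  )
}

#' ADC quantization model
#'
#' @param bits ADC resolution in bits (8 to 32; the device uses a 24-bit
#'   converter).
#' @param full_scale_min,full_scale_max Pressure full-scale range (mmHg);
#'   the device spans 0 to 240 mmHg.
#' @return An object of class `adc_model`.
#' @export
adc_model <- function(bits = 24, full_scale_min = 0, full_scale_max = 240) {
  stop_if_not_scalar(bits, "bits")
  if (bits < 8 || bits > 32 || bits != round(bits)) {
    stop("`bits` must be an integer in [8, 32]", call. = FALSE)
  }
  stop_if_not_scalar(full_scale_min, "full_scale_min")
  stop_if_not_scalar(full_scale_max, "full_scale_max")
  if (full_scale_max <= full_scale_min) {
    stop("`full_scale_max` must exceed `full_scale_min`", call. = FALSE)
  }
  structure(
    list(bits = as.integer(bits), full_scale_min = full_scale_min,
         full_scale_max = full_scale_max),
    class = "adc_model"
  )
}

#' Generate the arterial pulse waveform on a uniform time grid
#'
#' Evaluates the harmonic model at `round(duration * sample_rate)` samples
#' starting at t = 0.
#'
#' @param model A [pulse_wave_model()].
#' @param duration Length of the series (s, > 0).
#' @param sample_rate Sampling rate (Hz); must exceed twice the highest
#'   harmonic frequency (Nyquist).
#' @return Numeric vector of pressures (mmHg).
#' @export
generate_pulse <- function(model, duration, sample_rate) {
  stopifnot(inherits(model, "pulse_wave_model"))
  stop_if_not_scalar(duration, "duration", positive = TRUE)
  stop_if_not_scalar(sample_rate, "sample_rate", positive = TRUE)
  if (model$n_harmonics > 0) {
    f_max <- max(model$harmonics$frequency)
    if (sample_rate <= 2 * f_max) {
      stop(sprintf(
        "aliasing: sample_rate %.3g Hz is below the Nyquist rate for the %.3g Hz harmonic",
        sample_rate, f_max), call. = FALSE)
    }
  }
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  p <- rep(model$mean_pressure, n)
  h <- model$harmonics
  for (i in seq_len(model$n_harmonics)) {
    p <- p + h$amplitude[i] * sin(2 * pi * h$frequency[i] * t + h$phase[i])
  }
  p
}

#' Attenuate a pressure series through tissue
#'
#' Pointwise multiplication by `exp(-alpha)`: the whole signal (DC and AC
#' components) is scaled identically, matching the exponential tissue loss
#' model. Set `ac_only = TRUE` to attenuate only deviations from the series
#' mean (exploratory switch; the default is the literal full-signal model).
#'
#' @param series Pressure series (mmHg).
#' @param tissue A [tissue_model()] or a nonnegative scalar alpha.
#' @param ac_only If `TRUE`, only the AC component is attenuated.
#' @return Attenuated series (mmHg).
#' @export
apply_attenuation <- function(series, tissue, ac_only = FALSE) {
  alpha <- if (inherits(tissue, "tissue_model")) tissue$alpha else tissue
  stop_if_not_scalar(alpha, "alpha")
  if (alpha < 0) {
    stop("negative alpha would amplify the signal; out of model", call. = FALSE)
  }
  if (ac_only) {
    m <- mean(series)
    m + (series - m) * exp(-alpha)
  } else {
    series * exp(-alpha)
  }
}

#' Mechanical impedance of the tissue layer
#'
#' Returns the product `E * rho * c * d` of the tissue's elastic modulus,
#' density, sound speed and effective depth. Exposed for qualitative
#' exploration of how tissue stiffness relates to attenuation; it is not part
#' of the estimation path, and the product is dimensionally nonstandard for a
#' mechanical impedance, so treat it as a relative index only.
#'
#' @param tissue A [tissue_model()] with all four mechanical fields set.
#' @return Scalar impedance index.
#' @export
mechanical_impedance <- function(tissue) {
  stopifnot(inherits(tissue, "tissue_model"))
  fields <- c("elastic_modulus", "density", "sound_speed", "effective_depth")
  vals <- lapply(fields, function(nm) tissue[[nm]])
  if (any(vapply(vals, is.null, logical(1)))) {
    stop("mechanical_impedance needs elastic_modulus, density, sound_speed and effective_depth",
         call. = FALSE)
  }
  tissue$elastic_modulus * tissue$density * tissue$sound_speed *
    tissue$effective_depth
}

# Raised-cosine motion bump evaluated on time grid t.
motion_bump <- function(t, onset, duration, amplitude) {
  u <- (t - onset) / duration
  inside <- u >= 0 & u <= 1
  out <- numeric(length(t))
  out[inside] <- amplitude * 0.5 * (1 - cos(2 * pi * u[inside]))
  out
}

# Band-limited Gaussian noise with exact sample SD `sd_target` (0 allowed).
# bandwidth = Inf gives white noise.
bandlimited_noise <- function(n, sample_rate, sd_target, bandwidth) {
  if (sd_target == 0 || n < 2) return(numeric(n))
  z <- stats::rnorm(n)
  if (is.finite(bandwidth) && bandwidth < sample_rate / 2) {
    bf <- signal::butter(2, bandwidth / (sample_rate / 2), type = "low")
    z <- signal::filtfilt(bf, z)
  }
  s <- stats::sd(z)
  if (s == 0) return(numeric(n))
  z / s * sd_target
}

# Quantize pressures to the ADC grid (values clamped to full scale).
quantize_adc <- function(x, adc) {
  q <- (adc$full_scale_max - adc$full_scale_min) / 2^adc$bits
  x <- pmin(pmax(x, adc$full_scale_min), adc$full_scale_max)
  adc$full_scale_min + round((x - adc$full_scale_min) / q) * q
}

#' Synthesize a dual-channel sensor recording
#'
#' Composes the forward physics the processing pipeline assumes: the primary
#' transducer (over the artery) records the tissue-attenuated arterial pulse
#' plus the contact pressure; the reference transducer (off the artery)
#' records the contact pressure only. Baseline, drift, contact noise and
#' motion artifacts are shared across channels; each channel additionally
#' receives an independent instrument-noise draw, and both are optionally
#' quantized to the ADC grid.
#'
#' @param pulse A [pulse_wave_model()].
#' @param tissue A [tissue_model()].
#' @param contact A [contact_pressure_profile()].
#' @param adc An [adc_model()], or `NULL` to skip quantization.
#' @param duration Recording length (s, > 0).
#' @param sample_rate Sampling rate (Hz, > 0); default 100 Hz.
#' @param seed Integer seed; mandatory so every recording is reproducible.
#' @param quantize Apply ADC quantization (default `TRUE` when `adc` given).
#' @return A `dual_channel_recording`: list with `time` (s), `primary` and
#'   `reference` (mmHg), `sample_rate`, and `units` (`"mmHg"`).
#' @export
synthesize_recording <- function(pulse, tissue, contact, adc = adc_model(),
                                 duration = 60, sample_rate = 100, seed,
                                 quantize = !is.null(adc)) {
  stopifnot(inherits(pulse, "pulse_wave_model"),
            inherits(tissue, "tissue_model"),
            inherits(contact, "contact_pressure_profile"))
  stop_if_not_scalar(duration, "duration", positive = TRUE)
  stop_if_not_scalar(sample_rate, "sample_rate", positive = TRUE)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)

  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate

  arterial <- generate_pulse(pulse, duration, sample_rate)
  attenuated <- apply_attenuation(arterial, tissue)

  shared <- contact$baseline + contact$drift(t)
  if (!is.null(contact$motion_events)) {
    for (i in seq_len(nrow(contact$motion_events))) {
      ev <- contact$motion_events[i, ]
      shared <- shared + motion_bump(t, ev$onset, ev$duration, ev$amplitude)
    }
  }

  noise <- with_seed(seed, {
    list(
      contact = bandlimited_noise(n, sample_rate, contact$noise_sd,
                                  contact$noise_bandwidth),
      instr1 = stats::rnorm(n, 0, contact$instrument_noise_sd),
      instr2 = stats::rnorm(n, 0, contact$instrument_noise_sd)
    )
  })
  shared <- shared + noise$contact

  primary <- attenuated + shared + noise$instr1
  reference <- shared + noise$instr2
  if (quantize) {
    if (is.null(adc)) stop("`quantize = TRUE` requires an adc model", call. = FALSE)
    primary <- quantize_adc(primary, adc)
    reference <- quantize_adc(reference, adc)
  }

  structure(
    list(time = t, primary = primary, reference = reference,
         sample_rate = sample_rate, units = "mmHg"),
    class = "dual_channel_recording"
  )
}

#' @export
print.dual_channel_recording <- function(x, ...) {
  cat(sprintf(
    "Dual-channel recording: %d samples @ %g Hz (%.1f s), units %s\n",
    length(x$time), x$sample_rate, length(x$time) / x$sample_rate, x$units))
  cat(sprintf("  primary:   %.2f to %.2f mmHg\n", min(x$primary), max(x$primary)))
  cat(sprintf("  reference: %.2f to %.2f mmHg\n", min(x$reference), max(x$reference)))
  invisible(x)
}

#' Ground-truth beat pressures of a pulse model
#'
#' Numerically locates the systolic maximum and diastolic minimum of one
#' fundamental period of the harmonic waveform (on a fine grid), giving the
#' true per-beat SBP/DBP that a simulated recording encodes.
#'
#' @param pulse A [pulse_wave_model()] with at least one harmonic.
#' @param resolution Samples per fundamental period used for the search.
#' @return List with `sbp`, `dbp` and `pulse_pressure` (mmHg) and
#'   `heart_rate_hz` (fundamental frequency).
#' @export
true_beat_pressures <- function(pulse, resolution = 20000) {
  stopifnot(inherits(pulse, "pulse_wave_model"))
  if (pulse$n_harmonics == 0) {
    return(list(sbp = pulse$mean_pressure, dbp = pulse$mean_pressure,
                pulse_pressure = 0, heart_rate_hz = NA_real_))
  }
  f0 <- pulse$harmonics$frequency[1]
  t <- seq(0, 1 / f0, length.out = resolution)
  p <- rep(pulse$mean_pressure, resolution)
  h <- pulse$harmonics
  for (i in seq_len(pulse$n_harmonics)) {
    p <- p + h$amplitude[i] * sin(2 * pi * h$frequency[i] * t + h$phase[i])
  }
  list(sbp = max(p), dbp = min(p), pulse_pressure = max(p) - min(p),
       heart_rate_hz = f0)
}
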