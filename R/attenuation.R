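#' Estimate the tissue attenuation coefficient from amplitude ratios
#'
#' The arterial pulse loses amplitude exponentially through the overlying
#' tissue, so the lumped attenuation coefficient follows from the ratio of
#' the measured to the true arterial amplitude:
#' \deqn{\alpha = -\ln(P_{measured} / P_{arterial})}
#' Amplitudes should be AC (systolic peak minus diastolic foot) amplitudes:
#' contact-pressure offsets corrupt pointwise sample ratios, whereas AC
#' amplitudes are offset-free. Vectorized; the exact inverse of
#' [apply_attenuation()] by construction.
#'
#' @param measured_amplitude Amplitude recorded at the transducer (mmHg, > 0).
#' @param arterial_amplitude True arterial amplitude (mmHg, > 0), e.g. from a
#'   beat-to-beat reference monitor. Must be >= `measured_amplitude`
#'   (amplification is out of model).
#' @return Attenuation coefficient(s), dimensionless, >= 0.
#' @export
estimate_alpha <- function(measured_amplitude, arterial_amplitude) {
  if (length(measured_amplitude) != length(arterial_amplitude)) {
    stop("amplitude vectors must have equal length", call. = FALSE)
  }
  if (any(measured_amplitude <= 0) || any(arterial_amplitude <= 0)) {
    stop("amplitudes must be strictly positive", call. = FALSE)
  }
  if (any(measured_amplitude > arterial_amplitude)) {
    stop("measured amplitude exceeds arterial amplitude: negative alpha is out of model",
         call. = FALSE)
  }
  -log(measured_amplitude / arterial_amplitude)
}

#' Attenuation observations table
#'
#' One row per trial: the contact pressure held during the trial and the
#' attenuation coefficient estimated from it.
#'
#' @param contact_pressure Contact pressures (mmHg, > 0).
#' @param alpha Attenuation coefficients (> 0).
#' @param subject_id,trial_id Optional identifiers (recycled if scalar).
#' @return Data frame of class `alpha_observations`.
#' @export
alpha_observations <- function(contact_pressure, alpha,
                               subject_id = NA, trial_id = NA) {
  if (length(contact_pressure) != length(alpha)) {
    stop("`contact_pressure` and `alpha` must have equal length", call. = FALSE)
  }
  if (any(contact_pressure <= 0)) {
    stop("contact pressures must be strictly positive", call. = FALSE)
  }
  if (any(alpha <= 0)) stop("alpha values must be strictly positive", call. = FALSE)
  out <- data.frame(subject_id = subject_id, trial_id = trial_id,
                    contact_pressure_mmHg = as.numeric(contact_pressure),
                    alpha = as.numeric(alpha))
  class(out) <- c("alpha_observations", "data.frame")
  out
}

#' Summarize attenuation coefficients by contact-pressure level
#'
#' Grouped sample mean and sample standard deviation (n-1 denominator) of
#' alpha per contact-pressure level, as tabulated in static characterization.
#'
#' @param observations An [alpha_observations()] data frame (or any data
#'   frame with `contact_pressure_mmHg` and `alpha` columns).
#' @param levels Optional contact-pressure levels to report; levels with no
#'   observations are omitted with a warning.
#' @return Data frame with `contact_pressure_mmHg`, `mean_alpha`, `sd_alpha`,
#'   `n`.
#' @export
summarize_alpha <- function(observations, levels = NULL) {
  obs <- as.data.frame(observations)
  if (!all(c("contact_pressure_mmHg", "alpha") %in% names(obs))) {
    stop("need columns contact_pressure_mmHg and alpha", call. = FALSE)
  }
  if (nrow(obs) == 0) stop("no observations", call. = FALSE)
  if (is.null(levels)) {
    levels <- sort(unique(obs$contact_pressure_mmHg))
  } else {
    missing_lv <- setdiff(levels, obs$contact_pressure_mmHg)
    if (length(missing_lv) > 0) {
      warning(sprintf("no observations at contact pressure(s) %s; omitted",
                      paste(missing_lv, collapse = ", ")))
      levels <- setdiff(levels, missing_lv)
    }
  }
  rows <- lapply(levels, function(lv) {
    a <- obs$alpha[obs$contact_pressure_mmHg == lv]
    data.frame(contact_pressure_mmHg = lv, mean_alpha = mean(a),
               sd_alpha = if (length(a) > 1) stats::sd(a) else 0,
               n = length(a))
  })
  do.call(rbind, rows)
}

#' Fit the linear attenuation-versus-contact-pressure model
#'
#' Ordinary least squares for \eqn{\alpha = m P_c + b}: with increasing
#' contact pressure the tissue couples better to the transducer and the
#' attenuation coefficient decreases linearly (until structural changes such
#' as arterial occlusion, outside this model's validity). Accepts either
#' trial-level observations or a per-pressure mean table; both are exposed
#' because a summary table is sometimes all that is available.
#'
#' @param data An [alpha_observations()] data frame, a [summarize_alpha()]
#'   table (its `mean_alpha` column is used), or any data frame with columns
#'   `contact_pressure_mmHg` and `alpha`.
#' @return An `attenuation_fit`: `slope` (per mmHg), `intercept`
#'   (dimensionless), `residual_sd` (n-2 denominator), `n_points` and the
#'   fitted pressure range.
#' @export
fit_alpha_vs_pressure <- function(data) {
  d <- as.data.frame(data)
  if ("alpha" %in% names(d)) {
    y <- d$alpha
  } else if ("mean_alpha" %in% names(d)) {
    y <- d$mean_alpha
  } else {
    stop("need an `alpha` or `mean_alpha` column", call. = FALSE)
  }
  if (!"contact_pressure_mmHg" %in% names(d)) {
    stop("need a `contact_pressure_mmHg` column", call. = FALSE)
  }
  x <- d$contact_pressure_mmHg
  if (length(unique(x)) < 2) {
    stop("at least two distinct contact pressures are required", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  rsd <- if (length(x) > 2) sqrt(sum(res^2) / (length(x) - 2)) else 0
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         residual_sd = rsd,
         slope_se = rsd / sqrt(sum((x - mean(x))^2)),
         n_points = length(x),
         pressure_range = range(x)),
    class = "attenuation_fit"
  )
}

#' @export
print.attenuation_fit <- function(x, ...) {
  cat(sprintf(
    "Attenuation model: alpha = %.4g * Pc %+.4g (residual SD %.3g, n = %d, fitted over %g-%g mmHg)\n",
    x$slope, x$intercept, x$residual_sd, x$n_points,
    x$pressure_range[1], x$pressure_range[2]))
  invisible(x)
}

#' Predict the attenuation coefficient at a contact pressure
#'
#' Evaluates the fitted linear model `alpha = m * Pc + b`. Predictions are
#' confined to a 10-80 mmHg guard band around the fitted range: beyond it
#' the linear model has no support (at high pressures structural changes
#' such as arterial occlusion break linearity).
#'
#' @param fit An `attenuation_fit` (or a list with `slope` and `intercept`).
#' @param contact_pressure Contact pressure (mmHg).
#' @param guard Allowed prediction band (mmHg); default `c(10, 80)`.
#' @return Predicted alpha (> 0; an error otherwise).
#' @export
predict_alpha <- function(fit, contact_pressure, guard = c(10, 80)) {
  stop_if_not_scalar(contact_pressure, "contact_pressure", positive = TRUE)
  if (contact_pressure < guard[1] || contact_pressure > guard[2]) {
    stop(sprintf(
      "extrapolation: contact pressure %.3g mmHg outside the supported %g-%g mmHg band",
      contact_pressure, guard[1], guard[2]), call. = FALSE)
  }
  a <- fit$slope * contact_pressure + fit$intercept
  if (a <= 0) {
    stop("predicted alpha is nonpositive; outside the model's validity",
         call. = FALSE)
  }
  a
}

#' The device's published attenuation model
#'
#' Linear attenuation-versus-contact-pressure fit with slope -0.028 per mmHg
#' and intercept 5.56, characterized over 20-60 mmHg contact pressure.
#' Convenient default when no subject-specific static characterization is
#' available.
#'
#' @return An `attenuation_fit`.
#' @export
default_attenuation_fit <- function() {
  structure(
    list(slope = -0.028, intercept = 5.56, residual_sd = NA_real_,
         slope_se = NA_real_, n_points = 5L, pressure_range = c(20, 60)),
    class = "attenuation_fit"
  )
}
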