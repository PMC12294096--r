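#' Elliptical transducer contact geometry
#'
#' The transducer tip contacts the skin over an ellipse. The contact area is
#' computed from the semi-axes, `pi * (major/2) * (minor/2)`. The device's
#' datasheet area (62.53 mm^2) differs in the third decimal from the area
#' recomputed from its printed axes (62.57 mm^2); pass `area_mm2` to pin the
#' area to a measured value.
#'
#' @param major_axis_mm Full major-axis length (mm); default 11.89.
#' @param minor_axis_mm Full minor-axis length (mm); default 6.7.
#' @param area_mm2 Optional measured contact area (mm^2) overriding the
#'   computed ellipse area.
#' @return An object of class `ellipse_geometry` with an `area_mm2` field.
#' @export
ellipse_geometry <- function(major_axis_mm = 11.89, minor_axis_mm = 6.7,
                             area_mm2 = NULL) {
  stop_if_not_scalar(major_axis_mm, "major_axis_mm", positive = TRUE)
  stop_if_not_scalar(minor_axis_mm, "minor_axis_mm", positive = TRUE)
  if (major_axis_mm < minor_axis_mm) {
    stop("`major_axis_mm` must be >= `minor_axis_mm`", call. = FALSE)
  }
  if (is.null(area_mm2)) {
    area_mm2 <- pi * (major_axis_mm / 2) * (minor_axis_mm / 2)
  } else {
    stop_if_not_scalar(area_mm2, "area_mm2", positive = TRUE)
  }
  structure(
    list(major_axis_mm = major_axis_mm, minor_axis_mm = minor_axis_mm,
         area_mm2 = area_mm2),
    class = "ellipse_geometry"
  )
}

# Pa per mmHg, as used in the device's own calibration arithmetic (the
# rounded constant, not 133.322, so worked examples match to the last digit).
PA_PER_MMHG <- 133.3

#' Convert a calibration mass to contact pressure
#'
#' A mass `m` grams resting on the elliptical transducer tip exerts
#' `m g / area` pascals, converted to mmHg with the 133.3 Pa/mmHg constant:
#' \deqn{P = \frac{m g}{\pi (a/2)(b/2)} / 133.3}
#' Unit conversions (grams to kg, mm^2 to m^2) are handled internally.
#'
#' @param mass_g Mass in grams (>= 0); vectorized.
#' @param geometry An [ellipse_geometry()].
#' @param gravity Gravitational acceleration (m/s^2), default 9.81.
#' @return Pressure in mmHg.
#' @examples
#' weight_to_pressure(1, ellipse_geometry(area_mm2 = 62.53))  # ~1.17 mmHg
#' @export
weight_to_pressure <- function(mass_g, geometry = ellipse_geometry(),
                               gravity = 9.81) {
  stopifnot(inherits(geometry, "ellipse_geometry"))
  if (any(mass_g < 0)) stop("`mass_g` must be >= 0", call. = FALSE)
  stop_if_not_scalar(gravity, "gravity", positive = TRUE)
  force_n <- (mass_g / 1000) * gravity
  area_m2 <- geometry$area_mm2 * 1e-6
  (force_n / area_m2) / PA_PER_MMHG
}

#' Calibration weight set
#'
#' @param mass_g Masses in grams (strictly positive, unique). The device was
#'   calibrated with 10, 20, 50, 100, 200 and 500 g.
#' @param adc_counts ADC reading recorded for each mass.
#' @param gravity Gravitational acceleration (m/s^2).
#' @return An object of class `calibration_weight_set`.
#' @export
calibration_weight_set <- function(mass_g, adc_counts, gravity = 9.81) {
  if (length(mass_g) != length(adc_counts)) {
    stop("`mass_g` and `adc_counts` must have the same length", call. = FALSE)
  }
  if (length(mass_g) == 0) stop("empty weight set", call. = FALSE)
  if (any(mass_g <= 0)) stop("masses must be strictly positive", call. = FALSE)
  if (anyDuplicated(mass_g)) stop("masses must be unique", call. = FALSE)
  structure(
    list(mass_g = as.numeric(mass_g), adc_counts = as.numeric(adc_counts),
         gravity = gravity),
    class = "calibration_weight_set"
  )
}

#' Fit the linear ADC-to-pressure calibration
#'
#' Converts each calibration mass to its theoretical pressure via
#' [weight_to_pressure()] and fits the ordinary least-squares line mapping
#' ADC counts to mmHg.
#'
#' @param weights A [calibration_weight_set()] with at least two entries.
#' @param geometry An [ellipse_geometry()].
#' @return A `sensor_calibration`: slope (mmHg/count), intercept (mmHg),
#'   geometry, residual RMS (mmHg) and a timestamp.
#' @export
fit_adc_calibration <- function(weights, geometry = ellipse_geometry()) {
  stopifnot(inherits(weights, "calibration_weight_set"),
            inherits(geometry, "ellipse_geometry"))
  if (length(weights$mass_g) < 2) {
    stop("at least two calibration weights are required", call. = FALSE)
  }
  if (length(unique(weights$adc_counts)) < 2) {
    stop("all ADC readings identical: rank-deficient calibration fit",
         call. = FALSE)
  }
  pressure <- weight_to_pressure(weights$mass_g, geometry, weights$gravity)
  fit <- stats::lm(pressure ~ adc, data = data.frame(adc = weights$adc_counts,
                                                     pressure = pressure))
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         geometry = geometry,
         fit_residual_rms = sqrt(mean(stats::residuals(fit)^2)),
         n_weights = length(weights$mass_g),
         timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)),
    class = "sensor_calibration"
  )
}

#' @export
print.sensor_calibration <- function(x, ...) {
  cat(sprintf(
    "Sensor calibration: %.6g mmHg/count, intercept %.6g mmHg (RMS residual %.3g mmHg, n = %d)\n",
    x$slope, x$intercept, x$fit_residual_rms, x$n_weights))
  invisible(x)
}

#' Convert ADC counts to pressure with a fitted calibration
#'
#' @param calibration A `sensor_calibration` from [fit_adc_calibration()].
#' @param adc_counts ADC readings.
#' @return Pressure in mmHg.
#' @export
adc_to_pressure <- function(calibration, adc_counts) {
  stopifnot(inherits(calibration, "sensor_calibration"))
  calibration$intercept + calibration$slope * adc_counts
}

#' Theoretical ADC pressure resolution
#'
#' One least-significant-bit step of the converter over the full pressure
#' range: `(full_scale_max - full_scale_min) / 2^bits`. For the 24-bit,
#' 0-240 mmHg device this is 1.43e-5 mmHg.
#'
#' @param adc An [adc_model()].
#' @return Resolution in mmHg.
#' @export
theoretical_resolution <- function(adc = adc_model()) {
  stopifnot(inherits(adc, "adc_model"))
  (adc$full_scale_max - adc$full_scale_min) / 2^adc$bits
}

#' Daily calibration drift check
#'
#' Re-applies a previously fitted calibration to a set of check weights and
#' compares the predicted pressures with the theoretical mass-derived
#' pressures; sessions proceed only when every deviation is within tolerance.
#'
#' @param calibration A `sensor_calibration`.
#' @param check_weights A [calibration_weight_set()] of the day's readings.
#' @param tolerance Maximum acceptable absolute deviation (mmHg). Default
#'   0.5 mmHg, an order of magnitude below clinically relevant BP error.
#' @return A `drift_report`: data frame of per-weight deviations plus a
#'   `pass` flag and the tolerance.
#' @export
daily_check <- function(calibration, check_weights, tolerance = 0.5) {
  stopifnot(inherits(calibration, "sensor_calibration"),
            inherits(check_weights, "calibration_weight_set"))
  if (length(check_weights$mass_g) == 0) {
    stop("empty check set", call. = FALSE)
  }
  stop_if_not_scalar(tolerance, "tolerance", positive = TRUE)
  expected <- weight_to_pressure(check_weights$mass_g, calibration$geometry,
                                 check_weights$gravity)
  predicted <- adc_to_pressure(calibration, check_weights$adc_counts)
  tab <- data.frame(
    mass_g = check_weights$mass_g,
    expected_mmHg = expected,
    detected_mmHg = predicted,
    deviation_mmHg = predicted - expected
  )
  structure(
    list(table = tab, tolerance = tolerance,
         max_abs_deviation = max(abs(tab$deviation_mmHg)),
         pass = all(abs(tab$deviation_mmHg) <= tolerance)),
    class = "drift_report"
  )
}

#' @export
print.drift_report <- function(x, ...) {
  cat(sprintf("Daily calibration check: %s (max |deviation| %.3g mmHg, tolerance %.3g mmHg)\n",
              if (x$pass) "PASS" else "FAIL", x$max_abs_deviation, x$tolerance))
  print(x$table, row.names = FALSE)
  invisible(x)
}
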