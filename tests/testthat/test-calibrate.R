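test_that("weight_to_pressure reproduces the device's worked example", {
  geom <- ellipse_geometry(area_mm2 = 62.53)  # datasheet contact area
  expect_equal(weight_to_pressure(1, geom), 1.17, tolerance = 0.01)
  expect_equal(weight_to_pressure(0, geom), 0)
  # linear and homogeneous in mass
  expect_equal(weight_to_pressure(10, geom), 10 * weight_to_pressure(1, geom))
  masses <- c(1, 2, 4, 5, 10, 500)
  expect_equal(weight_to_pressure(masses, geom),
               masses * weight_to_pressure(1, geom))
})

test_that("ellipse area defaults to pi * semi-major * semi-minor", {
  geom <- ellipse_geometry(11.89, 6.7)
  expect_equal(geom$area_mm2, pi * (11.89 / 2) * (6.7 / 2))
  # printed axes give ~62.57 mm^2; the datasheet area differs only in the
  # third significant decimal so the 1 g worked example holds either way
  expect_equal(weight_to_pressure(1, geom), 1.17, tolerance = 0.01)
  expect_error(ellipse_geometry(5, 6.7), ">=")
  expect_error(ellipse_geometry(11.89, -1), "positive")
})

test_that("fit_adc_calibration inverts exact affine data to machine precision", {
  geom <- ellipse_geometry()
  masses <- c(10, 20, 50, 100, 200, 500)
  pressure <- weight_to_pressure(masses, geom)
  slope_true <- 0.02
  intercept_true <- -12.5
  counts <- (pressure - intercept_true) / slope_true
  cal <- fit_adc_calibration(calibration_weight_set(masses, counts), geom)
  expect_equal(cal$slope, slope_true, tolerance = 1e-12)
  expect_equal(cal$intercept, intercept_true, tolerance = 1e-9)
  expect_equal(cal$fit_residual_rms, 0, tolerance = 1e-9)
  # round trip: counts back through the calibration give the pressures
  expect_equal(adc_to_pressure(cal, counts), pressure, tolerance = 1e-9)
})

test_that("fit_adc_calibration recovers the slope under count noise", {
  geom <- ellipse_geometry()
  masses <- c(10, 20, 50, 100, 200, 500)
  pressure <- weight_to_pressure(masses, geom)
  slope_true <- 0.02
  counts_true <- pressure / slope_true
  set.seed(401)
  slopes <- replicate(50, {
    counts <- counts_true + rnorm(length(masses), sd = 20)
    fit_adc_calibration(calibration_weight_set(masses, counts), geom)$slope
  })
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - slope_true), 3 * se)
})

test_that("degenerate calibration inputs are rejected", {
  geom <- ellipse_geometry()
  expect_error(fit_adc_calibration(calibration_weight_set(10, 100), geom),
               "at least two")
  expect_error(
    fit_adc_calibration(calibration_weight_set(c(10, 20, 50), c(5, 5, 5)), geom),
    "rank-deficient")
  expect_error(calibration_weight_set(c(10, 10), c(1, 2)), "unique")
  expect_error(calibration_weight_set(c(-1, 10), c(1, 2)), "positive")
})

test_that("theoretical resolution matches the 24-bit device and halves per bit", {
  # 240 mmHg over 2^24 levels: 1.43e-5 mmHg (3 significant figures)
  expect_equal(theoretical_resolution(adc_model(24, 0, 240)), 1.43e-5,
               tolerance = 1e-3)
  expect_equal(theoretical_resolution(adc_model(16, 0, 240)), 240 / 2^16)
  expect_equal(theoretical_resolution(adc_model(16, 0, 240)), 0.003662,
               tolerance = 1e-4)
  for (b in c(8, 12, 16, 23)) {
    expect_equal(theoretical_resolution(adc_model(b, 0, 240)),
                 2 * theoretical_resolution(adc_model(b + 1, 0, 240)))
  }
  expect_error(adc_model(bits = 40), "\\[8, 32\\]")
  expect_error(adc_model(24, 10, 10), "exceed")
})

test_that("daily_check flags drift beyond tolerance and passes self-consistency", {
  geom <- ellipse_geometry()
  masses <- c(10, 20, 50, 100, 200, 500)
  pressure <- weight_to_pressure(masses, geom)
  counts <- (pressure - 1) / 0.02
  cal <- fit_adc_calibration(calibration_weight_set(masses, counts), geom)

  # readings generated from the fitted line: zero deviation, pass
  rep0 <- daily_check(cal, calibration_weight_set(masses, counts))
  expect_true(rep0$pass)
  expect_equal(rep0$table$deviation_mmHg, rep(0, length(masses)),
               tolerance = 1e-9)

  # readings offset by twice the tolerance: fail
  bad <- calibration_weight_set(masses, counts + 2 * 0.5 / 0.02)
  rep_bad <- daily_check(cal, bad, tolerance = 0.5)
  expect_false(rep_bad$pass)
  expect_equal(rep_bad$table$deviation_mmHg, rep(1, length(masses)),
               tolerance = 1e-9)

  expect_error(daily_check(cal, calibration_weight_set(numeric(0), numeric(0))),
               "empty")
})

test_that("a detected 1.23 mmHg against the printed 1.17 mmHg deviates by 0.06", {
  # the 1 g check as the device logs it: theoretical value printed to two
  # decimals (1.17), detected reading 1.23
  geom <- ellipse_geometry(area_mm2 = 62.53)
  printed <- floor(weight_to_pressure(1, geom) * 100) / 100
  expect_equal(printed, 1.17)
  expect_equal(1.23 - printed, 0.06, tolerance = 1e-9)
})
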