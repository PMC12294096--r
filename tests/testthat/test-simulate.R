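test_that("generate_pulse evaluates the harmonic sum on the time grid", {
  # empty harmonic sum: constant mean pressure
  p <- generate_pulse(pulse_wave_model(93), duration = 1, sample_rate = 100)
  expect_length(p, 100)
  expect_true(all(p == 93))

  # single unit harmonic: sin(pi/2) = 1 at t = 0.25 s
  m <- pulse_wave_model(0, data.frame(amplitude = 1, frequency = 1, phase = 0))
  p <- generate_pulse(m, duration = 1, sample_rate = 100)
  expect_equal(p[26], 1.0, tolerance = 1e-12)  # t = 25/100 s

  # over an integer number of cycles every sinusoid averages to zero exactly
  m2 <- pulse_wave_model(100, data.frame(amplitude = c(20, 8),
                                         frequency = c(1.2, 2.4),
                                         phase = c(0, 0)))
  p2 <- generate_pulse(m2, duration = 10, sample_rate = 250)
  expect_length(p2, 2500)
  expect_equal(mean(p2), 100, tolerance = 1e-9)
})

test_that("generate_pulse rejects sampling below the Nyquist rate", {
  m <- pulse_wave_model(0, data.frame(amplitude = 1, frequency = 10, phase = 0))
  expect_error(generate_pulse(m, 1, 15), "aliasing")
  expect_error(generate_pulse(m, 1, 20), "aliasing")  # exactly 2x still aliased
  expect_silent(generate_pulse(m, 1, 50))
})

test_that("pulse_wave_model enforces its invariants", {
  expect_error(pulse_wave_model(90, data.frame(amplitude = -1, frequency = 1,
                                               phase = 0)), ">= 0")
  expect_error(pulse_wave_model(90, data.frame(amplitude = 1, frequency = 0,
                                               phase = 0)), "positive")
  expect_error(pulse_wave_model(90, data.frame(amplitude = c(1, 1),
                                               frequency = c(2, 1),
                                               phase = c(0, 0))), "increasing")
  m <- canonical_pulse()
  expect_equal(m$n_harmonics, nrow(m$harmonics))
})

test_that("apply_attenuation scales the full signal by exp(-alpha)", {
  x <- c(90, 100, 110)
  expect_identical(apply_attenuation(x, 0), x)                 # e^0 = 1
  expect_equal(apply_attenuation(rep(100, 5), log(2)), rep(50, 5))
  # peak-to-foot amplitude scales identically
  p <- generate_pulse(canonical_pulse(), 10, 100)
  pa <- apply_attenuation(p, 4.5)
  expect_equal(max(pa) - min(pa), (max(p) - min(p)) * exp(-4.5),
               tolerance = 1e-12)
  expect_equal(max(pa) - min(pa), 46.26450 * exp(-4.5), tolerance = 1e-4)
  expect_error(apply_attenuation(x, -0.1), "amplif")
})

test_that("ac_only attenuation preserves the mean and scales deviations", {
  p <- generate_pulse(canonical_pulse(), 10, 100)
  pa <- apply_attenuation(p, 4.5, ac_only = TRUE)
  expect_equal(mean(pa), mean(p), tolerance = 1e-9)
  expect_equal(max(pa) - min(pa), (max(p) - min(p)) * exp(-4.5),
               tolerance = 1e-12)
})

test_that("mechanical_impedance is the literal product of its four factors", {
  expect_equal(mechanical_impedance(
    tissue_model(0, elastic_modulus = 1, density = 1, sound_speed = 1,
                 effective_depth = 1)), 1)
  z1 <- mechanical_impedance(tissue_model(0, 1e5, 1050, 1540, 0.003))
  expect_equal(z1, 1e5 * 1050 * 1540 * 0.003)  # = 4.851e8
  z2 <- mechanical_impedance(tissue_model(0, 2e5, 1050, 1540, 0.003))
  expect_equal(z2, 2 * z1)  # linear in each factor
  expect_error(mechanical_impedance(tissue_model(0, elastic_modulus = 1e5)),
               "needs")
})

test_that("synthesized recordings are deterministic in the seed", {
  pulse <- canonical_pulse()
  tiss <- tissue_model(4.5)
  contact <- contact_pressure_profile(40, drift = 0.01, noise_sd = 0.5)
  r1 <- synthesize_recording(pulse, tiss, contact, adc_model(), 10, 100, seed = 7)
  r2 <- synthesize_recording(pulse, tiss, contact, adc_model(), 10, 100, seed = 7)
  expect_identical(r1, r2)
  r3 <- synthesize_recording(pulse, tiss, contact, adc_model(), 10, 100, seed = 8)
  expect_false(identical(r1$primary, r3$primary))
})

test_that("seeded synthesis does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(synthesize_recording(canonical_pulse(), tissue_model(4.5),
                                 contact_pressure_profile(40, noise_sd = 0.5),
                                 adc_model(), 5, 100, seed = 42))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("channel difference reconstructs the pulse (conservation)", {
  pulse <- canonical_pulse()
  truth <- generate_pulse(pulse, 20, 100)

  # alpha = 0, no noise/drift, no quantization: subtraction inverts exactly
  rec <- synthesize_recording(pulse, tissue_model(0), quiet_contact(40),
                              adc = NULL, duration = 20, sample_rate = 100,
                              seed = 1, quantize = FALSE)
  expect_equal(rec$primary - rec$reference, truth, tolerance = 1e-12)

  # alpha = 0 with quantization: error bounded by one ADC step per channel
  q <- theoretical_resolution(adc_model())
  recq <- synthesize_recording(pulse, tissue_model(0), quiet_contact(40),
                               adc_model(), 20, 100, seed = 1)
  expect_lt(max(abs((recq$primary - recq$reference) - truth)), q + 1e-12)

  # alpha > 0, no quantization: e^alpha undoes the attenuation exactly
  rec2 <- synthesize_recording(pulse, tissue_model(4.5), quiet_contact(40),
                               adc = NULL, duration = 20, sample_rate = 100,
                               seed = 1, quantize = FALSE)
  expect_equal((rec2$primary - rec2$reference) * exp(4.5), truth,
               tolerance = 1e-9)
})

test_that("Fourier analysis of a clean pulse recovers harmonic structure", {
  # 10 s at 100 Hz: 12 and 24 full cycles, exact DFT bin alignment
  pulse <- pulse_wave_model(100, data.frame(amplitude = c(20, 8),
                                            frequency = c(1.2, 2.4),
                                            phase = c(0.4, 1.9)))
  x <- generate_pulse(pulse, 10, 100)
  n <- length(x)
  spec <- 2 * Mod(stats::fft(x)) / n
  freqs <- (seq_len(n) - 1) * 100 / n
  for (i in 1:2) {
    k <- which.min(abs(freqs - pulse$harmonics$frequency[i]))
    expect_equal(spec[k], pulse$harmonics$amplitude[i], tolerance = 0.02)
    # the harmonic is a genuine spectral peak
    expect_gt(spec[k], 10 * max(spec[c(k - 1, k + 1)]))
  }
})

test_that("ADC quantization moves no sample by more than one step", {
  adc <- adc_model(bits = 12, full_scale_min = 0, full_scale_max = 240)
  contact <- contact_pressure_profile(40, drift = 0.05, noise_sd = 0.5)
  rec_raw <- synthesize_recording(canonical_pulse(), tissue_model(4.5), contact,
                                  adc, 10, 100, seed = 3, quantize = FALSE)
  rec_q <- synthesize_recording(canonical_pulse(), tissue_model(4.5), contact,
                                adc, 10, 100, seed = 3, quantize = TRUE)
  step <- (adc$full_scale_max - adc$full_scale_min) / 2^adc$bits
  expect_lte(max(abs(rec_q$primary - rec_raw$primary)), step)
  expect_lte(max(abs(rec_q$reference - rec_raw$reference)), step)
})

test_that("contact noise lands on the reference channel at the stated SD", {
  contact <- contact_pressure_profile(40, drift = 0.02, noise_sd = 0.5,
                                      instrument_noise_sd = 0)
  rec <- synthesize_recording(pulse_wave_model(0), tissue_model(0), contact,
                              adc = NULL, duration = 60, sample_rate = 100,
                              seed = 11, quantize = FALSE)
  t <- rec$time
  resid <- rec$reference - 40 - 0.02 * t
  expect_lt(abs(sd(resid) - 0.5), 0.05)  # within 10% of the nominal SD
})

test_that("motion events appear as shared raised-cosine bumps", {
  ev <- data.frame(onset = 2, duration = 1, amplitude = 10)
  contact <- contact_pressure_profile(40, noise_sd = 0, motion_events = ev,
                                      instrument_noise_sd = 0)
  rec <- synthesize_recording(pulse_wave_model(0), tissue_model(0), contact,
                              adc = NULL, duration = 6, sample_rate = 100,
                              seed = 1, quantize = FALSE)
  # bump peaks at mid-event with the full amplitude, on both channels equally
  i_mid <- which.min(abs(rec$time - 2.5))
  expect_equal(rec$reference[i_mid], 50, tolerance = 1e-3)
  expect_equal(rec$primary, rec$reference)
  expect_true(all(abs(rec$reference[rec$time < 2 | rec$time > 3] - 40) < 1e-12))
})

test_that("true_beat_pressures matches a brute-force waveform search", {
  pulse <- canonical_pulse()
  tb <- true_beat_pressures(pulse)
  x <- generate_pulse(pulse, 1 / 1.2, 48000)
  expect_equal(tb$sbp, max(x), tolerance = 1e-6)
  expect_equal(tb$dbp, min(x), tolerance = 1e-6)
  expect_equal(tb$pulse_pressure, tb$sbp - tb$dbp)
})
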