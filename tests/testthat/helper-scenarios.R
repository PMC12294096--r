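# Shared fixtures: canonical pulse/tissue/contact models and a family of
# simulated subjects, all built in code at test time.

canonical_pulse <- function() {
  pulse_wave_model(100, data.frame(amplitude = c(20, 8),
                                   frequency = c(1.2, 2.4),
                                   phase = c(0, 2.2)))
}

quiet_contact <- function(baseline = 40) {
  contact_pressure_profile(baseline, noise_sd = 0, instrument_noise_sd = 0)
}

# Deterministic family of simulated subjects spanning realistic resting
# physiology: MAP 87-105 mmHg, fundamental 1.05-1.5 Hz, pulse amplitude
# 15-24 mmHg with a second harmonic at 40% amplitude.
make_subject <- function(i) {
  f0 <- 1.0 + 0.05 * i
  a1 <- 14 + i
  pulse_wave_model(85 + 2 * i,
                   data.frame(amplitude = c(a1, 0.4 * a1),
                              frequency = c(f0, 2 * f0),
                              phase = c(0, 2.2)))
}

# Alpha spread across subjects covering the characterized 3.9-5.0 range.
subject_alpha <- function(i) 3.9 + (5.0 - 3.9) * (i - 1) / 9
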