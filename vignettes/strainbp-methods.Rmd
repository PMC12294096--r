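---
title: "Methods: simulating and processing dual-transducer strain-gauge blood pressure signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and processing dual-transducer strain-gauge blood pressure signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainbp)
```

## The measurement problem

A strap-mounted wearable presses two strain-gauge pressure transducers
against the wrist: the *primary* transducer sits over the radial artery, the
*reference* transducer a few millimetres away, off the artery. Both see the
contact pressure the strap exerts on the skin; only the primary additionally
sees the arterial pulse, attenuated by the tissue between artery and sensor.
The signal model is

$$P_{1}(t) = P_a(t)\,e^{-\alpha} + P_c(t), \qquad P_{2}(t) = P_c(t),$$

where $P_a(t)$ is the arterial pressure waveform, $\alpha$ a lumped
dimensionless attenuation coefficient, and $P_c(t)$ the contact pressure.
The arterial waveform itself is modeled as a mean pressure plus harmonics of
the heart's contraction,

$$P_a(t) = P_{mean} + \sum_{n=1}^{N} A_n \sin(2\pi f_n t + \phi_n).$$

Subtracting the reference channel and multiplying by $e^{\alpha}$ recovers
$P_a(t)$; its per-beat systolic peaks and diastolic feet, affinely calibrated
against a beat-to-beat reference monitor, give continuous SBP/DBP.

Attenuation is written here with a single lumped exponent. A depth-resolved
form $e^{-\alpha d}$ is physically equivalent for our purposes because the
effective arterial depth $d$ is not separately measurable from these signals;
its effect is absorbed into $\alpha$, which is what the amplitude-ratio
estimator actually identifies.

## The synthetic-data generator

No public recordings exist for this class of device, so the package ships a
forward simulator (`synthesize_recording()`) that implements exactly the
model above plus the artifacts the pipeline must tolerate:

* **Contact baseline and drift.** A static hold-down pressure (default
  scenarios use 40 mmHg, the setting used for dynamic trials) plus a
  deterministic drift term (default 0.01 mmHg/s linear) emulating strap
  creep.
* **Contact noise, shared between channels.** Band-limited Gaussian noise
  (default SD 0.5 mmHg, bandwidth 0.3 Hz) models physiological and
  mechanical contact-pressure fluctuation — respiration, posture, strap
  mechanics. Both transducers ride the same rigid chassis under the same
  strap, so this fluctuation is common-mode: it appears identically on both
  channels and is what the reference-subtraction stage exists to remove. The
  0.3 Hz default reflects the dominant respiratory/vasomotor time scales;
  fluctuations much faster than the smoothing window would not be separable
  from the pulse by any subtraction scheme.
* **Instrument noise, independent per channel.** White Gaussian noise at
  0.005 mmHg SD by default. The hardware demonstrates AC waveform
  sensitivity well below 0.001 mmHg, so per-channel electronic noise is
  orders of magnitude below the contact fluctuation; it is kept as a separate
  parameter precisely because it is the component that subtraction *cannot*
  remove and that multiplication by $e^{\alpha} \approx 90$ amplifies.
* **Motion artifacts.** Raised-cosine pressure bumps (onset, duration,
  amplitude), shared across channels. The raised cosine is a smooth,
  compactly supported shape; nothing downstream depends on the exact form.
* **ADC quantization.** Rounding to the $2^{24}$-level grid over
  0–240 mmHg (1.43e-5 mmHg per step), switchable.

Randomness is always driven by an explicit seed, evaluated in a local RNG
scope, so identical configurations give byte-identical recordings and the
caller's RNG stream is untouched.

What the generator does **not** emulate: real arterial waveform morphology
(dicrotic notch shape beyond a second harmonic), beat-to-beat physiological
variability, arterial occlusion at high hold-down pressure, sensor
nonlinearity, and the reference monitor's own artifacts. Passing tests
therefore demonstrate that the processing chain correctly inverts the stated
physical model under realistic noise — not that the device performs to any
given accuracy on human subjects.

## Sensor calibration

Calibration weights placed on the transducer convert to pressure over the
elliptical contact area ($a$, $b$ the full axis lengths):

$$P_{mmHg} = \frac{m g}{\pi (a/2)(b/2)} \cdot \frac{1}{133.3}.$$

Two deliberate numerical choices: the Pa-to-mmHg constant is the rounded
133.3 (not 133.322) and gravity defaults to 9.81 m/s², so the package
reproduces the device's own worked numbers (1 g over the measured 62.53 mm²
area gives 1.177 → printed 1.17 mmHg). The semi-axis form is used even
though the conversion is sometimes written with $\pi a b$: only semi-axes
reproduce both the printed area and the printed 1 g pressure. The measured
area (62.53 mm²) and the area recomputed from the printed axes (62.57 mm²)
differ in the third decimal; `ellipse_geometry(area_mm2=)` lets either be
pinned.

`fit_adc_calibration()` is an ordinary least-squares line from ADC counts to
these pressures; `daily_check()` re-applies it to fresh readings and passes
when every deviation is within a tolerance (default 0.5 mmHg, an order below
clinically meaningful BP error — the standards grade devices at 5 mmHg).

## The processing pipeline

`estimate_bp()` chains five stages, each exposed separately:

1. **Low-pass filter** (`lowpass_filter()`): 4th-order Butterworth at 10 Hz,
   applied forward–backward for zero phase lag, on both channels. 10 Hz
   keeps the pulse harmonics that carry peak/foot morphology (fundamental
   1–3 Hz and the first few overtones) and removes movement noise. The
   series is extended by odd (point-mirrored) reflection before filtering,
   long enough for the filter's zero-state transient to decay below
   numerical noise, then trimmed — this keeps DC gain exactly 1 at the
   edges, which the common-mode-rejection property relies on.
2. **Reference smoothing** (`smooth_reference()`): centered moving average,
   default 1.0 s. The window shrinks *symmetrically* near the series ends,
   so constants and linear ramps (i.e., baseline plus drift) pass through
   unchanged everywhere; an asymmetric edge rule would bias the subtraction
   at the start of each recording. 1 s suppresses any pulse leakage into the
   reference while tracking drift and the slow shared contact noise.
3. **Isolation** (`isolate_arterial()`): $(P_1 - \tilde P_2)e^{\alpha}$. The
   $\alpha$ used here normally comes from `predict_alpha()` at the
   recording's contact pressure; the dynamic-trial default is the 40 mmHg
   prediction, $\alpha = 4.44$.
4. **Beat detection** (`detect_beats()`): prominence-based peak picking with
   a 0.33 s refractory interval (180 bpm ceiling); the diastolic foot is the
   minimum over the preceding inter-peak interval. The prominence floor is
   the larger of 30% of the robust (1st–99th percentile) signal range and an
   absolute 1 mmHg: a bump rising less than 1 mmHg in arterial units is not
   a credible beat, which is what keeps a pulseless recording from yielding
   noise beats. A dicrotic shoulder (second harmonic) produces at most a
   low-prominence secondary bump and is rejected by the floor, giving one
   beat per fundamental cycle. An empty result is a warning, not an error.
5. **BP mapping** (`fit_bp_calibration()`): affine maps peak→SBP and
   foot→DBP, least-squares over a calibration segment paired (nearest-peak,
   0.5 s tolerance) with the reference monitor's beats. With fewer than two
   distinct peak values the affine fit is rank-deficient and an offset-only
   map with unit gain is used. Estimates outside SBP 60–260 / DBP
   30–150 mmHg, or with SBP ≤ DBP, are flagged in the output table, never
   dropped. Isolation precedes map fitting, so the map absorbs residual
   scale error rather than attenuation itself.

Device–reference clock offset is handled by `estimate_lag()`
(cross-correlation, with a manual override emulating the protocol's
synchronization hand-tap), and per-beat pairing by `pair_nearest()`;
nearest-beat pairing was chosen over interpolation because the reference
monitor reports one value per beat, not a continuous curve.

## The attenuation model

`estimate_alpha()` inverts the attenuation law from AC (peak-minus-foot)
amplitudes, $\alpha = -\ln(P_{measured}/P_{arterial})$. AC amplitudes rather
than pointwise sample ratios: any contact-pressure offset in the measured
signal corrupts a pointwise ratio but cancels in peak-minus-foot. Measured
amplitude above arterial amplitude (negative $\alpha$) is rejected —
tissue cannot amplify.

Static characterization across hold-down pressures yields per-level mean ±
SD tables (`summarize_alpha()`, $n-1$ denominators) and the linear model
$\alpha = m P_c + b$ (`fit_alpha_vs_pressure()`): coupling improves with
pressure, so $\alpha$ falls linearly until structural changes (occlusion)
break the model — predictions are therefore guarded to a 10–80 mmHg band and
must stay positive. Fitting accepts either trial-level observations or a
per-level mean table, because published characterizations sometimes provide
only the means. On the characterized means (5.0, 4.8, 4.5, 4.2, 3.9 at
20–60 mmHg) the slope is −0.028 per mmHg; note that least squares on those
means puts the intercept at 5.60, whereas the device's published intercept
is 5.56 — consistent with the original fit having used trial-level data.
`default_attenuation_fit()` carries the published pair (−0.028, 5.56).

## Agreement statistics

`agreement()` reports MAE ± SD, Pearson $r$, and Bland–Altman bias with 95%
limits of agreement. Conventions, stated because they are genuinely
ambiguous in the field: the "± SD" attached to an MAE is the sample SD of
the *absolute* differences; all SDs use $n-1$; the LoA multiplier is the
standard 1.96 (published LoA values for this device class are not always
reconstructible as bias ± 1.96·SD, so the standard definition is implemented
rather than any inferred multiplier); $r$ is reported as `NA` with a warning
when a series is constant. `bhs_grade()` applies the British Hypertension
Society tiers (A: ≥60/85/95% of absolute errors within 5/10/15 mmHg, B:
≥50/75/90, C: ≥40/65/85, else D) and `aami_check()` the AAMI limits (|mean
error| ≤ 5 mmHg, SD ≤ 8 mmHg).

## What the simulation studies use

The test suite and examples run desk-scale problems chosen to resolve the
quantities they check: 60 s recordings at 100 Hz (100 Hz resolves pulse
morphology up to the 10 Hz filter corner with margin; no acquisition rate is
inherent to the method), ten simulated subjects spanning MAP 87–105 mmHg,
fundamentals 1.05–1.5 Hz and $\alpha$ 3.9–5.0, and 200-replicate Monte Carlo
runs for regression-recovery checks. Under the dynamic-trial conditions
(40 mmHg contact pressure, 0.5 mmHg shared contact noise, drift,
quantization) the end-to-end beat MAE lands near 2.5–3.5 mmHg — the same
scale as validated hardware — and collapses below 0.1 mmHg as noise goes to
zero.

```{r example}
pulse <- pulse_wave_model(100, data.frame(amplitude = c(20, 8),
                                          frequency = c(1.2, 2.4),
                                          phase = c(0, 2.2)))
alpha <- predict_alpha(default_attenuation_fit(), 40)
rec <- synthesize_recording(pulse, tissue_model(alpha),
                            contact_pressure_profile(40, drift = 0.01,
                                                     noise_sd = 0.5),
                            adc_model(), duration = 60, sample_rate = 100,
                            seed = 1)
est <- estimate_bp(rec, filter_spec(), alpha, identity_bp_map())
est
true_beat_pressures(pulse)[c("sbp", "dbp")]
```

## Known limitations

* The harmonic pulse model is stationary within a recording; dynamic BP
  ramps (exercise protocols) are emulated by comparing across scenarios, not
  within one recording.
* Fully independent wide-band noise at the contact-pressure scale on the
  primary channel is *not* recoverable by this (or any two-channel
  subtraction) architecture once $e^{\alpha}$ amplification is applied; the
  shared/independent noise split in the generator encodes the physical
  reason the real device works, and results are conditional on it.
* The lumped $\alpha$ is constant per recording; slow within-recording
  attenuation changes (tissue creep) are not modeled.
* `mechanical_impedance()` computes the literal product $E\rho c d$, which
  is dimensionally nonstandard for an impedance; it is exposed for
  qualitative exploration only and feeds nothing downstream.
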