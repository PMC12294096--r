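Package: strainbp
Title: Dual-Transducer Strain-Gauge Cuffless Blood Pressure Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, calibration, signal processing and validation tools
    for a dual-transducer strain-gauge wearable blood pressure monitor. A
    physics-based generator synthesizes two-channel contact-pressure
    recordings (harmonic arterial pulse attenuated by overlying tissue,
    riding on a shared contact-pressure baseline with drift, noise, motion
    artifacts and ADC quantization). The processing pipeline converts raw
    recordings to beat-by-beat systolic and diastolic pressure via zero-phase
    low-pass filtering, reference-channel smoothing and subtraction,
    exponential un-attenuation, beat detection and affine calibration against
    a beat-to-beat reference monitor. Companion modules implement weight-based
    sensor calibration over the elliptical contact area, estimation of the
    tissue attenuation coefficient and its linear dependence on contact
    pressure, and device-agreement statistics (MAE, Pearson correlation,
    Bland-Altman limits of agreement, BHS grading and the AAMI accuracy
    criterion).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
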