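Package: respirad
Title: Unconstrained Respiratory Measurement and Swallowing-Pause Detection
    with Millimeter-Wave Radar
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to estimate chest displacement from pulse-coherent
    millimeter-wave radar sweeps by range-bin selection, phase extraction,
    unwrapping and phase-to-distance conversion; to slice displacement
    traces into sliding windows and compute a 40-dimensional designed
    feature vector (inter-quantile movement ranges, autocorrelation, FFT
    magnitudes, waveform histogram); to train and evaluate class-weighted
    classifiers of respiring, breath-holding and swallowing
    (deglutition-apnea) intervals with macro-averaged F1 scoring; and to
    validate radar-derived waveforms against a band-type reference sensor.
    A synthetic sweep simulator generates quasi-periodic breathing,
    commanded breath-holds and short swallow pauses with realistic radar
    phase noise, so the whole pipeline is testable without human
    recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    e1071,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
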