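Package: ssvepdetect
Title: SSVEP Detection, Flicker Stimulus Design and Personalization for
    Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for steady-state visual evoked potential (SSVEP)
    brain-computer interfaces built around a calibrated threshold detector on
    Welch power spectral density features. Provides parametric checkerboard
    flicker stimuli (squares and single- to triple-layer flickering circles)
    with per-frame flicker schedules, a synthetic occipital EEG generator
    emulating a rest/stimulation trial protocol, zero-phase bandpass and notch
    preprocessing, per-frequency baseline calibration with resting and
    stimulated thresholds, rule-based classification of six commands plus an
    idle state from the largest and second-largest gated spectral features,
    two-stage personalized stimulus selection combining accuracy with comfort
    ratings, and evaluation utilities including the Wolpaw information
    transfer rate.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    png,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
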