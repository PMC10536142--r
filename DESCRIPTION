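Package: rehabband
Title: Pressure-Sensor Wristband Action Recognition for Wrist Rehabilitation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Recognition of wrist rehabilitation exercises from a three-channel
    thin-film pressure-sensor wristband sampled at 15 Hz. Provides
    hysteresis-aware piecewise-linear sensor calibration, resting-reference
    signal normalization, a two-rule sliding-window action pre-detection gate,
    an autoencoder for dimensionality reduction, a one-vs-one linear SVM voting
    classifier over four rehabilitation actions, model-selection utilities
    (k-fold hyperparameter grids, a generalized k-fold linear-separability
    test, confusion-matrix metrics), a streaming detector, and a fully seeded
    synthetic signal generator that stands in for the wearable hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
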