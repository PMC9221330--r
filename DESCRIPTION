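Package: physiofuse
Title: Multi-Modal Physiological Feature Fusion for Flight-Behavior Recognition
Version: 0.1.0
Authors@R:
    person("physiofuse", "developers", email = "physiofuse@example.org",
           role = c("aut", "cre"))
Description: End-to-end toolkit for recognizing flight maneuvers (takeoff, level
    flight, turn-and-hover, roll, somersault, stall) from five wearable
    physiological channels (ECG, GSR, EMG, respiration, skin temperature).
    Provides a reproducible synthetic cohort simulator with known ground truth,
    signal preprocessing (normalization, percentage-rule artifact handling,
    wavelet/IIR filtering, R-peak detection, downsampling), sliding-window
    extraction of a 28-dimensional fused feature vector (heart-rate variability
    time and frequency statistics, electrodermal level statistics, surface EMG
    amplitude and spectral statistics, respiration statistics), Pearson/Kendall
    feature screening against subjective difficulty ratings, a
    confidence-weighted voting ensemble of four tree-based classifiers
    implemented natively (CART, extremely randomized trees, gradient boosting,
    second-order Newton boosting), and 10-fold / leave-one-subject-out
    cross-validation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
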