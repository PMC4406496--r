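Package: noceeg
Title: Linear and Non-Linear EEG Measures for Nociceptive-Response
    Prediction During Sedation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measurement and evaluation toolkit for predicting nociceptive
    responses from single-channel frontal EEG recorded during
    procedural sedation.  Computes spectral measures (band powers,
    weighted mean frequency, spectral edge frequencies) and non-linear
    auto-mutual-information measures (Shannon and Renyi) on EEG filtered
    in the traditional delta/theta/alpha/beta bands and in high-frequency
    bands (60-95 Hz, 105-145 Hz) where scalp and facial EMG dominates.
    Includes pre-event window segmentation with drug-stability
    truncation, artifact suppression, prediction-probability (Pk)
    evaluation with leave-one-out discriminant classification, a
    randomized constrained feature-subset search, and a synthetic
    sedation-recording generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
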