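Package: nogodecode
Title: Data-Driven Decoding of Response-Inhibition Performance from Go/Nogo EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for predicting inter-individual response
    inhibition performance ("good" vs "bad" performers) from epoched Go/Nogo
    EEG. Implements the behavioral speed-accuracy ratio and median-split group
    formation, artifact rejection, spherical-spline current source density,
    ERP averaging and peak/mean-amplitude quantification, Morlet
    continuous-wavelet total power, subject-by-feature banks over time,
    channel and frequency, hybrid t-test + sequential floating forward
    selection (SFFS) with an RBF-kernel support vector machine, k-fold
    confidence-bound accuracy curves, and train/validation, permutation and
    feature-omission verification. Ships a synthetic multi-subject EEG cohort
    generator with plantable ground-truth components so every stage is
    testable without acquired data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    data.table,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
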