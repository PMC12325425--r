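Package: dfnc
Title: Dynamic Functional Network Connectivity State Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates recurring functional connectivity states from
    component time courses of resting-state fMRI. Implements post-ICA
    time-series cleaning (detrending, despiking, zero-phase Butterworth
    low-pass), tapered sliding-window covariance with graphical-LASSO
    regularization and Fisher z-transformation, k-means clustering of
    windowed connectivity into brain states with elbow-based model
    selection, temporal state metrics (mean dwell time, fractional
    windows, transition count), nonparametric and edgewise group
    statistics with FDR control, and exploratory linear-SVM
    classification with leave-one-out cross-validation. A synthetic
    cohort generator with hidden-Markov state switching and planted
    group differences supplies ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    signal,
    e1071,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
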