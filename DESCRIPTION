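Package: eegfatigue
Title: EEG-Based Fatigue Detection with Two-Level Sparse RBF Networks
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for binary brain-state classification
    (fatigue vs. alert) from multichannel EEG recordings. Provides
    deterministic signal preprocessing (polyphase resampling, zero-phase
    Butterworth band-pass filtering, fixed-window epoching and per-epoch
    principal component feature extraction), a sparse radial basis function
    classifier trained by regularized orthogonal least squares with a
    D-optimality selection cost, particle swarm optimization of the three
    learner hyperparameters (regularization, kernel width, D-optimality
    weight), confusion/ROC/cross-validation evaluation, and a synthetic
    two-state EEG generator with an alpha-band (8-13 Hz) power contrast so
    the whole pipeline is testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
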