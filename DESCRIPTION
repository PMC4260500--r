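Package: wmload
Title: Cross-Task EEG Decoding of Working-Memory Load
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and single-trial decoding of working-memory load (WML)
    from oscillatory EEG. Provides paradigm schedulers for controlled
    working-memory tasks (numerical n-back, reading span) and realistic
    learning tasks (algebra word problems, alternating theorem/comic study
    windows), a synthetic-EEG forward model with a frontal-midline theta /
    parietal alpha workload signature, EOG regression, keypress-safe
    activation and resting interval extraction, Burg autoregressive spectral
    estimation, percent event-related desynchronization/synchronization
    (%ERD/ERS) features, subjective-rating based class labeling with
    difficulty-level calibration, and SVM-RBF classification with
    within-task cross-validation and cross-task permutation testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
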