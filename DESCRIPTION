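Package: hrvprint
Title: Heart Rate Variability and Heartprint Indices for Imminent
    Ventricular Tachyarrhythmia Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes heart rate variability (HRV) and premature
    ventricular complex (PVC) "heartprint" indices from beat-annotated
    RR-interval recordings, and selects index combinations and RBF
    support-vector-machine hyperparameters by patient-paired 10-fold
    cross-validation with a greedy forward search.  Includes a synthetic
    paired-cohort RR-series generator so the whole pipeline is testable
    without access to implantable-defibrillator recordings, min-max
    feature scaling fitted on training data only, ROC/AUC evaluation
    with confidence intervals, and plain-text model serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
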