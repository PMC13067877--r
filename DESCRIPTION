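Package: arscore
Title: Arrhythmic Risk Scoring with Populations of Human Ventricular Cell Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A standardized in silico framework for drug-induced proarrhythmia
    classification. Provides the O'Hara-Rudy (2011) endocardial human
    ventricular action potential model with conductance-scaling hooks, Latin
    hypercube populations of models with stability filtering and experimental
    calibration, pore-block drug application from IC50/Hill parameters, eight
    action-potential instability biomarkers, a monodomain electrotonically
    coupled tissue mode on hexahedral meshes, a weighted Arrhythmic Risk Score
    (ARS) with ROC-AUC biomarker weights and optimized three-class thresholds,
    validation statistics (leave-one-out cross-validation, permutation test,
    bootstrap confidence intervals), and a subsampling / biomarker-reduction
    robustness study. Synthetic waveform and event generators make every stage
    testable without long simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    lhs,
    methods,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
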