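Package: osahrv
Title: Heart Rate Variability and Oximetry Profiling for Obstructive Sleep Apnea Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for screening obstructive sleep apnea (OSA)
    severity from beat-to-beat RR-interval (RRi) series and overnight oxygen
    saturation traces. Provides spurious-beat correction with a moving-median
    band filter, automated selection of hourly 15-minute analysis segments, a
    34-index heart rate variability profile (time domain, Welch-type spectral
    band powers, detrended fluctuation analysis, seven entropy estimators,
    Max-Min and binary symbolic dynamics, heart rate fragmentation, asymmetry
    indices, and phase-rectified signal averaging), oximetry summary metrics
    (minimum saturation, time below 90 percent), and random-forest severity
    classification with SMOTE class balancing, stratified cross-validation,
    bootstrap AUROC confidence intervals, DeLong tests for correlated ROC
    curves, and impurity-based feature ranking. A seeded synthetic cohort
    generator emulates the statistical structure of sleep recordings across
    severity classes so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    randomForest,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
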