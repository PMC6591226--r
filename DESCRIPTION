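Package: ppgmiles
Title: Pulse-Wave Morphometry and Multiple-Instance Detection of
    Obstructive Hypertrophic Cardiomyopathy from Wrist PPG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening obstructive hypertrophic cardiomyopathy
    (oHCM) from resting wrist photoplethysmography (PPG). Provides a seeded
    generator of synthetic healthy and oHCM wrist-PPG cohorts with known
    ground-truth beat landmarks, beat segmentation and qualification,
    a fixed catalog of 42 morphometric pulse-wave features per beat,
    subject-level nonparametric group comparison with Bonferroni
    correction, a MILES (multiple-instance learning via embedded instance
    selection) classifier with a 1-norm support-vector machine producing a
    per-recording oHCM score, and a leave-one-subject-out cross-validation
    harness with ROC, bootstrap confidence intervals and Youden operating
    point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
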