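Package: ckdstrata
Title: Stratified Urinary-Peptide Classifiers of Rapid CKD Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates baseline-eGFR-stratum-specific urinary
    peptide classifiers of rapid chronic kidney disease (CKD) progression.
    Provides a synthetic cohort generator with zero-inflated log-normal
    peptide amplitudes and longitudinal eGFR trajectories, housekeeping
    peptide normalization, eGFR-slope outcome labeling, per-stratum
    Wilcoxon/Benjamini-Hochberg biomarker discovery, support vector machine
    panel training with take-one-out backward reduction, cross-stratum ROC
    validation with DeLong confidence intervals, and clinical comparator
    models (albuminuria, the 4-variable Kidney Failure Risk Equation,
    CKD-EPI eGFR, Cox proportional hazards).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    e1071,
    pROC,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
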