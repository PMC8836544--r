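Package: ctrcdval
Title: External Validation of Cardiotoxicity Risk Models for Trastuzumab-Treated Breast Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to externally validate pre-treatment risk prediction models for
    cancer-therapeutics-related cardiac dysfunction (CTRCD) in women receiving
    trastuzumab for HER2+ breast cancer. Provides a declarative scoring engine with
    shipped configurations for a points-based heart-failure risk model, the NSABP B-31
    cardiac risk score, and the HFA-ICOS trastuzumab risk proforma; rule-based CTRCD
    adjudication from serial left-ventricular ejection fraction measurements under the
    CREC, ESC, and ASE definitions; discrimination (AUC with DeLong confidence
    intervals), calibration, and contingency-table inference; and a seeded synthetic
    cohort generator so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    splines,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
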