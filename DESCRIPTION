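Package: cardioscore
Title: Point-Based Risk Scores for Cardiovascular Events in Diabetes Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates point-based risk scores for acute
    myocardial infarction and non-AMI sudden cardiac death from
    electronic-health-record style cohorts of patients with type 2
    diabetes. Implements cohort and outcome derivation from raw
    patient/episode/laboratory tables, two-stage Cox proportional-hazards
    predictor selection, decile-based detection of J/U-shaped
    hazard relationships with data-driven cut-off derivation, a
    hazard-ratio-band point-assignment rule, discrimination metrics
    (ROC/AUC with DeLong intervals, Harrell's concordance) with a
    cross-validation harness, and a synthetic cohort generator with
    known ground truth for validating every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    pROC,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
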