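Package: sarcscreen
Title: Validation of the Ishii Score Chart for Sarcopenia Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to validate sarcopenia screening instruments against the
    AWGS2019 reference standard. Implements the sex-specific Ishii score
    chart and calf-circumference screens, the AWGS2019 case definition,
    diagnostic-accuracy metrics (sensitivity, specificity, predictive
    values, likelihood ratios, Youden index), empirical ROC curves with AUC
    and DeLong or bootstrap confidence intervals, Youden-optimal cut-off
    selection, exhaustive reconstruction of 2x2 contingency tables from
    published rounded metrics, and a calibrated Gaussian-copula synthetic
    cohort generator for end-to-end testing when individual-level study
    data are unavailable.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, MASS, jsonlite
Suggests: testthat (>= 3.0.0), pROC, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
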