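Package: appsval
Title: External Validation Toolkit for the APPS ARDS Mortality Score
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for external validation of the APPS, a 3-9 point
    prognostic score for hospital mortality in moderate or severe acute
    respiratory distress syndrome (ARDS) built from age, PaO2/FiO2 ratio
    and maximal airway pressure. Implements the original and recalibrated
    cutoff sets as instances of a general cutoff-table score, seeded
    synthetic cohort simulation with a logistic mortality mechanism,
    stratum odds-ratio tables with trend tests, ROC analysis with DeLong
    confidence intervals and Youden-optimal cutoffs, Hosmer-Lemeshow
    calibration with an automated cutoff-search recalibration,
    Kaplan-Meier stratified survival, cohort input/output and a
    command-line validation report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
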