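Package: gacalib
Title: Regression Calibration for Measurement Error in Gestational Age
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Corrects measurement error in gestational age (GA) assessed by
    fundal height (FH) and last menstrual period (LMP) against a partially
    observed ultrasound gold standard using regression calibration, and
    propagates the correction into bias-adjusted logistic-regression
    associations of GA with neonatal mortality and low birth weight.
    Provides a synthetic-cohort generator with a classical measurement-error
    structure, Bland-Altman agreement statistics, preterm classification,
    two-stage bootstrap standard errors that account for calibration
    uncertainty, and an ultrasound-availability sensitivity analysis, plus
    an end-to-end study pipeline with CSV/JSON reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
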