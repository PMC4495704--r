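Package: psindex
Title: Procedure-Based Severity Index for Inpatient Mortality Risk Adjustment
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derivation, scoring and validation of a procedure-based severity
    index for acute-care inpatients from administrative claims-style data.
    Implements the full derivation pipeline (prevalence and chi-square
    screening of admission-day procedures, phi-coefficient consolidation of
    collinear indicators, multivariable logistic regression, and Sullivan-style
    integer point assignment anchored to the Charlson comorbidity index), the
    published 19-procedure point table, a validation battery (c-statistic with
    DeLong intervals, integrated discrimination improvement, the omega
    variance-ratio statistic, Hosmer-Lemeshow and per-index-value calibration),
    Quan's ICD-10 Charlson comorbidity coding, and a seeded synthetic-cohort
    generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
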