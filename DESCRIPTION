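Package: scrinhf
Title: Scoring and Concordance Analysis for Heart Failure Self-Management Instruments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the 12-item Partners in Health (PIH) long-form
    chronic-disease self-management questionnaire into its four domain
    subtotals, bands every scale into the four ordinal self-management
    categories (good, average, borderline, poor), computes the SCRinHF
    short-form binary triage score and its long-form-derived equivalent,
    and cross-tabulates the two instruments to estimate concordance.
    Includes category-vs-readmission contingency analysis (uncorrected
    Pearson chi-squared and an enumeration-based exact test), 12-month
    outcome classification (readmission composite, worsening renal
    function, failure to attend), concurrent- and predictive-validity
    linear fits with covariate adjustment, and a latent-trait synthetic
    cohort generator so the full pipeline runs without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
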