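Package: svdscores
Title: Composite Cerebral Small-Vessel-Disease Scores and Longitudinal
    Cognitive-Decline Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based computation of the hypertensive-arteriopathy (HA-SVD),
    cerebral-amyloid-angiopathy (CAA-SVD), and modified CAA-SVD composite MRI
    scores from rated small-vessel-disease imaging markers, together with the
    longitudinal memory-clinic analysis built on them: variance-gated two-sample
    comparisons, paired within-group tests, logistic regression of 1-year
    Clinical Dementia Rating worsening with a Firth fallback, ROC cutoff
    derivation with the Youden index, and a synthetic two-group cohort
    generator calibrated to published group summaries for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    yaml
Suggests:
    car,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
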