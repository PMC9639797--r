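Package: recallscreen
Title: Story-Recall Speech Screening Analysis for Cognitive Impairment and
    Amyloid Status
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for evaluating automatic story recall as a
    screening instrument for mild cognitive impairment (MCI) and amyloid
    beta positivity. Provides a synthetic cohort and transcript generator
    emulating a 2x2 amyloid-by-diagnosis case-control design; transcript
    normalisation, word error rate and directed text-pair feature
    extraction with per-story averaging; tournament leave-pair-out
    cross-validated logistic-regression classification; ROC inference
    (DeLong variance, confidence intervals, paired tests, Youden-index
    operating points, Cohen's kappa, AUC-detection power); and
    deterministic screening simulations (primary-care MCI screening
    against the MMSE, and amyloid-PET pre-screening enrichment).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
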