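Package: fibropep
Title: Urinary Peptidomics Classification of Renal Interstitial Fibrosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for grading renal interstitial fibrosis and
    tubular atrophy (IFTA) from CE-MS urinary peptide peak lists: internal
    standard normalization, IFTA-based group assignment with covariate-matched
    cohort construction, frequency-filtered Wilcoxon rank-sum biomarker
    discovery under Benjamini-Hochberg FDR control, a support-vector-machine
    peptide panel classifier with leave-one-out validation, ROC evaluation
    with Youden operating points and exact binomial confidence intervals,
    score-IFTA rank correlation, and observed-mode protease cleavage-site
    inference. A zero-inflated log-normal cohort generator reproduces the
    statistical structure of the reference cohort design so every stage is testable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
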