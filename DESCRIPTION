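Package: eyetriage
Title: Rule-Based Surgical Decision Support and Agreement Evaluation for
    Highly Myopic Cataract
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for triaging highly myopic cataract eyes (axial length
    > 26 mm) into four surgical recommendation categories with a
    configurable five-step clinical decision rule, and for evaluating
    automated graders and raters against a gold standard. Includes
    visual-acuity handling (Snellen/logMAR/categorical codes, prediction
    error metrics), LOCS III grade evaluation (Re1.0, ICC(2,1), binary
    diagnostic metrics, ROC/AUC with DeLong comparison), multi-rater
    agreement (confusion matrices, percent consistency, Cohen's kappa,
    kappa reconstruction from marginals, special-case subsets, heatmaps),
    a seeded synthetic cohort generator calibrated to published summary
    statistics, and consolidated cohort reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
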