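Package: pamtriage
Title: Text Classification of Emergency Calls for Prehospital Major Trauma Triage
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements a hybrid text-classification pipeline for identifying
    prehospital-activated major trauma (PAMT) cases from emergency-call
    transcripts. The pipeline combines dictionary-aware word segmentation,
    stop-word removal and synonym grouping; term frequency-inverse document
    frequency (TF-IDF) feature ranking and selection; an expert-keyword
    rule gate; and a Bernoulli naive Bayes classifier with Laplace
    smoothing. An evaluation harness provides repeated random subsampling
    cross-validation with fixed validation-class composition, diagnostic
    accuracy metrics (sensitivity, specificity, predictive values, Youden
    index), certainty-level stratification, learning curves, and feature
    co-occurrence analysis. A synthetic corpus generator with a
    class-conditional keyword model makes every stage testable without
    access to confidential call recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
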