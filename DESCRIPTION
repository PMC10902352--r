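Package: sudoeval
Title: Evaluating Probabilistic Classifiers Without Ground-Truth Labels via
    Pseudo-Label Discrepancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate probabilistic binary (and multi-class)
    classifiers on unlabelled, distribution-shifted deployment data.
    Scores are discretized into probability intervals; within each interval,
    sampled points are temporarily assigned each candidate class
    (pseudo-labels) and lightweight probe classifiers are trained to separate
    them from ground-truth points of the opposing class.  The signed
    discrepancy in probe performance on a labelled held-out set (SUDO)
    quantifies class contamination per interval without any deployment
    labels.  Includes threshold-based prediction tiering, the
    reliability-completeness curve and its area (AURCC) for label-free model
    comparison, group-stratified bias audits, and a simulated Gaussian
    benchmark suite for validating the method against known contamination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    pROC,
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
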