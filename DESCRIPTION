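Package: healr
Title: Heuristic-Enabled Active Learning for Partially Labelled Tabular Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pool-based active learning in which the human oracle is replaced
    by a certainty-sampling heuristic: per iteration a gradient-boosted
    classifier scores the unlabelled pool, the score distribution is split at
    a classification boundary, and quartile-derived dynamic cut-offs (sup on
    the positive side, inf on the negative side) admit only high-confidence
    samples as pseudo-labels.  Includes benchmark competitors (uncertainty and
    random sampling against a simulated oracle), the accompanying
    preprocessing stack (z-score normalisation, Pearson-correlation
    redundancy filtering, SMOTE class balancing, out-of-bag permutation
    feature importance), gene-set feature engineering (Jaccard redundancy
    graphs, exact maximum-weight independent set selection, Fisher's exact
    enrichment features over a protein-association network), and synthetic
    data generators for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
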