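Package: linkstack
Title: Link Prediction with Topological Features, Recursive Feature
    Elimination and Stacked Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Supervised link prediction for undirected, unweighted
    networks. Twelve topological similarity indices (common neighbours,
    preferential attachment, Adamic-Adar, Leicht-Holme-Newman, resource
    allocation, average commute time, matrix forest index, random walk
    with restart, SimRank, local path, local and superposed random
    walks) are computed per node pair and used as features. A random
    forest drives recursive feature elimination with Gini variable
    importance and cross-validated subset scoring, and a two-level
    stacking ensemble (regularised logistic regression, gradient
    boosted trees and extreme gradient boosting as base learners, with
    an extreme-gradient-boosting fuse model trained on out-of-fold
    predictions) produces link probabilities. Includes balanced
    edge/non-edge dataset construction, rank-based AUC and confusion
    metrics, matching-score diagnostics, multi-run aggregation with the
    F-test/t-test comparison protocol, synthetic network generators for
    benchmarking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    MASS,
    ranger,
    xgboost,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
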