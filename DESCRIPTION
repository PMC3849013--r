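Package: regmln
Title: Markov Logic Networks for Supervised Gene Regulatory Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised inference of directed gene regulatory networks from
    heterogeneous gene descriptors encoded in first-order logic. Gene
    expression under perturbation, Gene Ontology biological processes,
    subcellular protein localization, protein-protein interactions and
    chromosomal locations are turned into ground atoms; Horn rules concluding
    on a Regulates predicate are induced by a bottom-clause guided top-down
    search; per-rule weights are learned as a non-recursive Markov Logic
    Network by l2-penalized conditional log-likelihood; class imbalance is
    handled by asymmetric bagging. Includes a tensor-product pairwise-kernel
    SVM baseline, ROC/precision-recall evaluation with three network-completion
    study protocols, and a synthetic-data generator with planted rules.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    kernlab,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
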