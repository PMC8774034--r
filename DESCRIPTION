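Package: mdgae
Title: miRNA-Disease Association Prediction with Collaborative Graph
    Autoencoders
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts unobserved miRNA-disease associations from a binary
    association matrix and side-information similarity networks.  Two graph
    autoencoders -- one convolving over the miRNA similarity graph, one over
    the disease similarity graph -- are trained collaboratively under a
    joint objective that combines a self-attention (neural inductive matrix
    completion) term with label-propagation-style reconstruction terms.
    Includes Gaussian interaction-profile kernel similarity, MeSH-style DAG
    semantic similarity (hierarchy-decay and information-content models),
    five-fold cross-validation with AUROC/AUPR and fixed-specificity
    metrics, a planted low-rank synthetic-data generator, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
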