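Package: mspcd
Title: Multi-Source Similarity Fusion and Hierarchical Neural Networks for
    circRNA-Disease Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts circRNA-disease associations by fusing five similarity
    models -- Levenshtein sequence similarity, Jaccard functional similarity
    over disease/GO/miRNA annotation profiles, Gaussian interaction profile
    (GIP) kernels for circRNAs and diseases, and two DAG-based disease
    semantic similarity models -- into per-entity feature vectors, and scoring
    pairs with a hierarchical neural network (two feature towers, element-wise
    interaction, deep classifier head). Includes balanced negative sampling,
    stratified k-fold cross-validation, an independent-split protocol, a
    baseline-classifier harness, unknown-pair ranking, a synthetic-data
    generator with planted cluster structure, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    nnet,
    optparse,
    randomForest,
    stats,
    utils
Suggests:
    igraph,
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
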