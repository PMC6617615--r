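Package: mgcnn
Title: Molecular Graph Convolutional Networks for Multilabel Compound
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Multilabel classification of small molecules into biosynthetic
    starting-substance categories with a molecular graph convolutional
    neural network (MGCNN): distance-indexed graph convolution over the
    atom-bond graph, neighborhood max-pooling, a sum-gather readout and
    independent paired-softmax category heads trained with Adam under
    dropout.  Includes five-fold and leave-one-out cross-validation
    harnesses with per-category accuracy reports and multilabel count
    statistics, fingerprint and descriptor baselines (random forest,
    neural network, support vector machine) with correlation-network
    feature selection, and a seeded synthetic molecule generator with
    rule-based multilabels so the whole stack is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    ChemmineOB,
    ChemmineR,
    e1071,
    igraph,
    jsonlite,
    methods,
    nnet,
    randomForest,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
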