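Package: htinet
Title: Herb-Target Interaction Prediction from Heterogeneous Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts herb-protein target interactions from a typed,
    multi-layer heterogeneous network of herbs, symptoms, diseases, drugs
    and proteins. Node embeddings are learned with second-order biased
    random walks (node2vec) and skip-gram negative sampling, candidate
    (herb, protein) pairs are featurized by the Hadamard product of their
    embeddings, and supervised classifiers (KNN, SVM, logistic regression,
    decision tree, random forest, gradient boosting) score candidate pairs
    under 10-fold cross-validation with AUROC/AUPR reporting. Includes the
    PRINCE network-propagation baseline, similarity-layer construction
    (cosine, Jaccard, min-max normalization, Fisher's exact filtering),
    and a planted-signal synthetic network generator for end-to-end
    benchmarking without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    igraph,
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    e1071,
    rpart,
    randomForest,
    xgboost
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nnet,
    pROC,
    withr
Config/testthat/edition: 3
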