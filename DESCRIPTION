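Package: essembler
Title: Essential-Gene Classification from DNA Sub-Word Embeddings and
    Stacked Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-classification toolkit for essential-gene
    identification from nucleotide sequences alone. DNA sequences are
    tokenized into overlapping n-gram "biological sub-words", embedded
    with a continuous bag-of-words language model trained from scratch
    (softmax, hierarchical-softmax or negative-sampling loss), and
    averaged into fixed-length feature vectors. Five base classifiers
    (k-nearest neighbours, random forest, RBF support vector machine,
    multi-layer perceptron and a 1-D convolutional network) are combined
    by stacked generalization with an ordinary-least-squares
    meta-learner on out-of-fold probabilities. Includes SVM-variant
    SMOTE oversampling applied strictly inside training folds, a
    repeated stratifiable five-fold cross-validation protocol with
    sensitivity/specificity/accuracy/MCC/AUC reporting, k-mer and
    pseudo k-tuple nucleotide composition baseline featurizers, and a
    synthetic-data generator with planted hexamer motifs for end-to-end
    validation without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    e1071,
    randomForest,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    Biostrings,
    yaml
Config/testthat/edition: 3
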