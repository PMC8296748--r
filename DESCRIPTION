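Package: gatnet
Title: Graph Attention Networks with Attention Pooling for Weighted
    Brain-Network Classification and Interpretation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns to classify weighted functional connectivity networks
    with a graph attention network (GAT2) whose graph-level readout is a
    learnable attention pooling head, and interprets the trained model by
    learning a global node-feature mask and by gradient saliency, evaluating
    explanations through feature perturbation (change of prediction
    probability, label flips, metric deltas). Includes construction of
    connectivity graphs from region time series (Pearson correlation,
    absolute-value edge weights, optional threshold sparsification), a
    seeded synthetic labelled-graph generator for benchmarking, fivefold
    cross-validation with early stopping, a metric suite (accuracy,
    sensitivity, specificity, F1, AUC, MCC), and standard baselines
    (linear SVM, PCA+SVM, random forest, MLP, CNN).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    e1071,
    ranger
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
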