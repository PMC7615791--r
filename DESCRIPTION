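Package: dagae
Title: Distribution-Regularized Adversarial Graph Autoencoder for Brain
    Functional Network Augmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates class-conditional brain functional networks (BFNs)
    with a distribution-regularized adversarial graph autoencoder whose
    generator is a stack of connectivity-transformer (multi-head
    self-attention) layers. Latent node representations learned by a
    two-layer graph-convolutional encoder are regularized towards a
    class-conditional kernel-density prior by an adversarial
    discriminator, and decoded back to weighted connectivity matrices by
    an inner-product head. Includes a synthetic two-class connectome
    cohort simulator, Pearson BFN construction, stratified
    cross-validation with leakage-safe augmentation, GCN/SVM/DNN
    downstream classifiers, weighted graph metrics and a 2-D embedding
    diagnostic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    e1071,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml,
    ggplot2
Config/testthat/edition: 3
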