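Package: perturbnet
Title: Sparse Gaussian Chain-Graph Models of SNP Perturbation Cascades
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Learns two-layer sparse conditional Gaussian graphical models
    (sCGGMs) that represent the cascade of influence from genetic variants to
    a gene network and from the gene network to a clinical-trait network.
    Provides an alternating Newton coordinate-descent solver with active
    sets, warm starts and line search; a memory-budgeted block-wise variant
    of the same solver; BIC-based regularization selection; a semi-supervised
    EM algorithm for samples with missing expression profiles; inference
    procedures for network-mediated SNP effects on traits, their
    decomposition over gene modules, and the posterior (moralized) gene
    network; ground-truth simulators with scale-free modular networks; and a
    sensitivity-versus-FDR evaluation and robustness harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    glmnet,
    jsonlite,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
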