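Package: tensorGO
Title: Multi-View Latent Tensor Reconstruction for Gene Ontology Term
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multi-view, multi-label prediction of Gene Ontology (GO) terms
    from heterogeneous protein features (sequence embeddings, domain
    fingerprints, protein-protein interaction profiles). The core model is a
    factorized higher-order polynomial regression: the weight tensor over
    cross-view feature products is represented in CP form with a second-level
    factorization of the factor matrices and optional ReLU activations, and is
    trained by mini-batch gradient descent under unit-norm constraints. The
    package also provides the GO label-processing pipeline (OBO parsing,
    true-path propagation, label-space selection, conditional information
    content), protein-centric CAFA evaluation metrics (Fmax, weighted Fmax,
    Smin, AUPRC, AUROC, coverage), frequency and sequence-similarity transfer
    baselines, homology-aware cluster-grouped cross-validation, and a
    synthetic-data generator so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
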