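Package: drivermux
Title: Driver Gene Prioritization from Multiplex Directed Gene Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes cancer driver genes by integrating several gene-gene
    interaction networks (directed and undirected) over a shared gene set with
    continuous multi-omics features. Node representations are learned with a
    directed graph convolution whose per-node message weights balance incoming
    against outgoing neighborhoods using directional Dirichlet energies and
    learnable degree embeddings. Label scarcity in the positive-unlabeled
    setting is addressed by entropy- and cluster-constrained pseudo-positive
    augmentation and by one-class internal contrastive learning that infers a
    high-confidence negative gene set. Includes infomax-style multiplex
    contrastive pretraining with a consensus embedding, a cross-validation
    harness with AUROC/AUPRC/F1, class-imbalance experiments, interaction-count
    analysis against known driver genes, and a synthetic multiplex-graph
    generator with planted directional class signal. Model training runs on a
    small built-in reverse-mode automatic differentiation engine with an AdamW
    optimizer, so no external deep-learning runtime is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
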