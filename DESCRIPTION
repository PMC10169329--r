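Package: gklink
Title: Gaussian-Kernel Linear-Optimization Link Prediction for
    miRNA-lncRNA Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts missing links in bipartite miRNA-lncRNA interaction
    networks. Gaussian interaction-profile kernel similarities (or
    sequence, expression, or functional-annotation similarities) are fused
    with the observed 0/1 interaction matrix into an integrated adjacency,
    and a closed-form ridge-type linear-optimization model produces a
    rating matrix whose bipartite block ranks candidate interactions.
    Includes readers for edge-list, FASTA, expression and annotation
    inputs, a repeated k-fold and leave-one-out cross-validation harness
    with midrank AUC, a seeded planted-block synthetic-data generator, and
    a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
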