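Package: bganmda
Title: miRNA-Disease Association Prediction with a Bidirectional
    Adversarial Similarity-Network Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts unobserved miRNA-disease associations from known
    association tables, miRNA sequences and disease ontology structure.
    Integrates sequence, functional and Gaussian interaction profile
    kernel similarity for miRNAs with two directed-acyclic-graph
    semantic similarity models and a Gaussian kernel for diseases, then
    trains a bidirectional adversarial network (encoder, generator,
    discriminator) on the concatenated per-pair similarity feature
    vectors and ranks candidate pairs by the discriminator's
    association score.  Ships repeated k-fold and leave-one-out
    cross-validation protocols with per-fold similarity recomputation,
    a full metric panel (AUC, AUPR, F1, recall, precision, MCC), and a
    seeded synthetic-data generator with planted low-rank block
    structure for download-free end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
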