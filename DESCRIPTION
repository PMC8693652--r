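Package: scregnet
Title: Single-Cell Coexpression Modules and Master-Regulator Networks for
    Disease Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end single-cell RNA-seq analysis pipeline for finding
    master-regulator transcription factors of a disease phenotype in
    iPSC-derived neurons: quality control and marker-based subtype
    classification, negative-binomial Wald differential expression between
    genotypes, k-nearest-neighbour smoothing of normalised counts,
    signed-hybrid weighted coexpression modules with topological overlap,
    eigengene-trait association and bootstrap stability scoring, mutual
    information regulatory-network inference with data-processing-inequality
    pruning, and two-tailed master-regulator analysis with concordance
    filtering. Ships a synthetic-data generator with planted cell classes,
    modules, and perturbed regulators so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    DESeq2,
    Matrix,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    fgsea,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
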