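Package: mmint
Title: Integrated miRNA-mRNA Differential Expression and Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for integrating paired miRNA and mRNA
    count data from a two-condition RNA-seq experiment. Provides negative
    binomial differential expression with median-of-ratios normalisation and
    moderated moment dispersion estimates, multi-resource miRNA target
    prediction consensus with expression anti-correlation filtering,
    zero-order protein-protein interaction subnetwork assembly with topology
    metrics, and hypergeometric gene-set over-representation with kappa-score
    term grouping. A fully seeded synthetic-data module generates count
    matrices, prediction tables, interactomes and gene-set collections with
    planted ground truth so every stage can be validated by recovery of known
    miRNA-target repressions.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
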