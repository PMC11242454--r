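Package: rhizocomm
Title: Growth-Linked Rhizosphere Microbiome Analysis with Assembly Null
    Models and Co-Occurrence Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking plant growth performance to rhizosphere
    microbiome structure from amplicon feature tables. Implements the
    post-denoising filtering chain (singleton removal, replicate prevalence
    filter, total-sum scaling), core-microbiome partitioning, growth-trait
    clustering (k-means and Ward hierarchical clustering with ANOSIM),
    alpha/beta diversity (weighted UniFrac, PCoA, PERMANOVA, pairwise
    Wilcoxon with FDR), null-model partitioning of community assembly
    processes (beta-mean-nearest-taxon distance, betaNTI, Raup-Crick
    Bray-Curtis), and compositional genus-level co-occurrence networks
    (clr transform, Pearson sparsification with local FDR, greedy
    modularity modules, eigenvector-centrality hubs, spectral robustness).
    A seeded synthetic-data generator with controllable assembly regimes
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    cluster,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    withr
LinkingTo: Rcpp
Suggests:
    mclust,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
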