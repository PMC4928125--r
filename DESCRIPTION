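Package: cladeshift
Title: Comparative Molecular Evolution of Gene Families Between Two Plant Clades
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reproducible pipeline for comparing the molecular
    evolution of gene families between grasses and eudicots: construction of
    clusters of orthologous groups from all-vs-all protein similarity tables,
    distance-based gene trees with bootstrap support, rule-based inference of
    old and recent gene duplications and losses, pairwise dN/dS estimation
    (Nei-Gojobori counting) with randomized clade comparisons, maximum
    likelihood codon models (GY94/F3x4 one-ratio, two-ratio branch, and M3
    discrete site models) with likelihood ratio tests and empirical Bayes
    detection of positively selected sites, and a moment estimator of type-II
    functional divergence between subfamily clusters. A seeded synthetic
    gene-family generator emits sequences plus truth logs so every stage is
    verifiable without external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    phytools,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
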