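Package: phyloturn
Title: Temporal Phylogenetic Turnover in Repeat-Census Forest Plots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies temporal phylogenetic turnover between two censuses
    of a mapped forest dynamics plot using Rao quadratic entropy, and
    standardizes it against two null models: species-name shuffling across
    the phylogeny, and a demographic null model that re-simulates mortality
    (species- and size-class-specific survival) and recruitment (observed
    recruit-to-parent dispersal distances around randomly chosen conspecific
    mature stems). Downstream statistics relate turnover to phylogenetic
    similarity: net relatedness index with independent-swap randomization,
    Blomberg's K phylogenetic signal tests, simultaneous autoregressive
    error regression on quadrat lattices, and PCNM-based variation
    partitioning with forward selection. Includes a synthetic census
    generator with tunable dispersal, survival, habitat-filtering and
    phylogenetic density-dependence so the whole pipeline can be exercised
    without restricted plot data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    picante,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
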