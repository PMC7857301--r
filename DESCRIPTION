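Package: rescueSim
Title: Individual-Based Eco-Evolutionary Simulation of Extinction Risk and
    Genetic Rescue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward-time, individual-based, non-Wright-Fisher simulator for
    studying extinction risk driven by recessive strongly deleterious
    variation in small populations. Models an exome-scale diploid genome with
    a gamma distribution of fitness effects, selection-dependent dominance
    (hs relationship, two-class hmix, or fixed h), viability selection with
    carrying-capacity density dependence, environmental stochasticity
    (Ornstein-Uhlenbeck carrying capacity), and random catastrophes.
    Provides demographic scenarios for population contraction (instantaneous
    and gradual) and genetic rescue by translocation from source populations
    of varying demographic history, with migrant-screening strategies, plus
    per-generation summary statistics (heterozygosity, F_ROH, fitness,
    binned deleterious-allele counts) and replicate-level extinction-time
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    optparse,
    Rcpp,
    GenomicRanges,
    IRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    VariantAnnotation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
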