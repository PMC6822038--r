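Package: phyloniche
Title: Climatic Niche Evolution of Host-Specialized Herbivores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolution of climatic niches on a
    time-calibrated phylogeny, with an emphasis on host-specialized
    phytophagous insects and their host plants. Builds per-species climatic
    trait matrices from occurrence records and bioclimatic rasters;
    estimates phylogenetic signal by maximum-likelihood Pagel's lambda with
    a likelihood-ratio test; computes disparity-through-time curves on
    standardized multivariate climate traits with a Brownian-motion
    simulation envelope; and runs kernel-density niche equivalency tests
    (environmental PCA, corrected occupancy grids, Schoener's D,
    pooled-split permutations) between an insect and the pooled range of
    its host plants. Includes a synthetic-data generator (Yule trees,
    lambda-transformed Brownian traits, gradient climate rasters,
    suitability-weighted occurrence sampling) so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    jsonlite
Suggests:
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
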