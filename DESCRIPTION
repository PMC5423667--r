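Package: skagerrak
Title: Population Structure and Temperature-Gated Larval Drift for Invasive Oysters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess connectivity of invasive Pacific oyster
    (Crassostrea gigas) populations across a dispersal barrier such as the
    Skagerrak. One arm analyses diploid microsatellite genotypes: per-locus
    diversity statistics (observed and expected heterozygosity, rarefied
    allelic richness, private alleles), Monte-Carlo Hardy-Weinberg and
    linkage-disequilibrium tests with Benjamini-Yekutieli false-discovery-rate
    thresholds, Cavalli-Sforza-Edwards chord distances with bootstrap
    neighbour-joining trees, principal coordinates analysis, and pairwise
    Weir-Cockerham F_ST with permutation tests. The other arm simulates
    passive super-individual larval drift on gridded ocean fields with a
    degree-day development clock and a temperature threshold at settlement,
    summarising landings on a coarse coastal grid. Synthetic genotype and
    ocean-scenario generators with known ground truth make every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
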