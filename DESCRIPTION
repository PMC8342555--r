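Package: consgen
Title: Neutral and Adaptive Conservation Genetics for Fragmented Fish
    Populations
Version: 1.0.0
Authors@R: person("consgen", "developers", email = "consgen@example.org",
    role = c("aut", "cre"))
Description: Dual-marker conservation-genetics toolkit combining neutral
    microsatellite analyses (diversity, Hardy-Weinberg and linkage exact
    tests, Weir-Cockerham F-statistics, R_ST, G_ST, isolation by distance,
    bottleneck detection, M-ratio, admixture-model Bayesian clustering with
    Evanno delta-K) with adaptive MHC class II beta-1 domain analyses
    (amplicon read filtering and allele validation, Nei-Gojobori dN/dS with
    Jukes-Cantor correction and codon bootstrap, physicochemical z-descriptor
    supertype classification, haplotype and nucleotide diversity, phi_ST).
    Includes forward and coalescent simulators for microsatellite genotypes,
    amplicon read sets and codon alignments so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    MASS,
    cluster,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite
Config/testthat/edition: 3
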