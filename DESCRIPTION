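Package: hemivar
Title: Variant Discovery and Prioritization for Targeted Resequencing of
    Hemizygous Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, testable re-implementation of a targeted
    deep-resequencing analysis for X-linked loci sequenced in hemizygous
    males: a paired-end read simulator with known ground truth, a hashed
    k-mer seed mapper with local Smith-Waterman alignment, pileup-based
    haploid genotype calling, functional and conservation annotation,
    rare-variant prioritization at evolutionarily conserved sites,
    population-genetic summaries (Watterson's theta, nucleotide diversity,
    Tajima's D), position-weight-matrix scanning of regulatory sites with
    background-calibrated z-scores, and closing statistics (Poisson
    frequency bounds, Welch's t-test on reporter-assay ratios, family
    segregation classification).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
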