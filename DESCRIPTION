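Package: neoxmap
Title: Linkage Mapping and QTL Analysis for F2 Intercrosses with Neo-Sex Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing F2 intercross genotype data in species carrying
    neo-sex chromosomes, motivated by crosses of the mountain pine beetle
    (Dendroctonus ponderosae). Provides a synthetic cross simulator with
    X-hemizygous inheritance and neo-Y read-contamination artifacts, a
    cross-design-aware genotype filter cascade, multipoint genetic-map
    estimation with a genotyping-error hidden Markov model, EM interval mapping
    with X-specific permutation thresholds and Bayes credible intervals, Marey
    map inversion detection and local recombination-rate estimation, minimal
    crossover counting with sex comparisons, and male/female coverage-based
    stratification of the X chromosome.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    GenomicRanges,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
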