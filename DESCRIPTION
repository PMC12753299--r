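Package: microdepth
Title: Sequencing-Depth Bias in Metagenomic Intraspecies Diversity Estimates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and profiling toolkit for studying how uneven
    sequencing (coverage) depth biases metagenomic estimates of microbial
    intraspecies diversity. Generates strain-mixture metagenomes with
    defined pairwise ANI, log-normal abundances and per-base sequencing
    error profiles (error-free, Q20, Q30); recruits reads to a reference
    with identity filtering; computes nucleotide diversity (pi), average
    nucleotide identity of reads (ANIr), sequencing depth and breadth from
    per-position pileups; and quantifies depth-dependent bias through
    rarefaction (diversity ratios and average absolute errors).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
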