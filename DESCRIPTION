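Package: mitopop
Title: Population Structure Analysis of Mitochondrial Control-Region Haplotypes
Version: 0.1.0
Authors@R: person("Mitopop", "Developers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for intraspecific phylogeography from aligned
    mitochondrial control-region sequences: molecular diversity indices
    (haplotype and nucleotide diversity with Nei's standard errors,
    segregating sites, transition/transversion counts), AMOVA-based
    fixation indices (Phi-ST) with permutation tests and Wright's gene-flow
    transformation, Tajima's D and Fu's Fs neutrality tests with
    coalescent-simulation significance, mismatch-distribution fitting of the
    sudden-expansion model (tau, theta0, theta1) with conversion of tau to
    calendar years, and median-joining haplotype networks. Includes a
    coalescent-style synthetic-data generator with population structure and
    sudden demographic growth so that every stage is testable without
    external downloads, plus a command-line driver that reproduces the full
    analysis layout from a FASTA alignment and a population map.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
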