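Package: geneconflict
Title: Population-Genetic Models of Trait Distorters and Their Suppressors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic gamete-frequency recursions, invasion and stability
    analysis, and stochastic agent-based simulations of intragenomic conflict
    between selfish trait distorters and their costly suppressors. Provides
    single-locus and two-locus recursions for distorter-suppressor
    coevolution, Jacobian-based invasion criteria, adaptive-dynamics analysis
    of distorter strength, a deterministic long-term introduction-suppression
    cycle model with a separation-of-timescales approximation for average
    trait distortion, and forward-time agent-based simulators of genome-wide
    conflict between a 'cabal' of distorter loci and the suppressing majority
    of the genome.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
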