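Package: frustfree
Title: Frustration-Free Beta-Sheet Topologies and Lattice Protein Designability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing why a handful of protein superfolds dominate
    structural databases, restricted to pure parallel beta-sheet topologies.
    Enumerates all strand-order topologies up to the left-right flip, classifies
    each by crossover-connection clashes, jumps, frustrated alpha-beta-unit
    pairings and a topology-level relative contact order, and computes the
    occurrence frequency of homologous groups in a topology (OFHT) over an
    ECOD-like domain classification table.  Includes an exhaustive
    two-dimensional lattice HP model augmented with sequence-independent
    penalty motifs, with full designability scans over all conformations and
    all HP sequences, plus seeded synthetic-data generators so every analysis
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    withr,
    optparse,
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
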