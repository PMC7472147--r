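Package: viroscout
Title: Virus Discovery from Shotgun Metagenomes by Subtraction, Ensemble
    Assembly, and Translated Homology Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A desk-scale viral metagenomics pipeline: paired-end read
    simulation with realistic library artefacts, duplicate removal by a
    positional key, Phred quality tail and adaptor trimming, host and
    bacterial read subtraction by ungapped seed-and-extend alignment,
    multi-k de Bruijn graph assembly with partitioned sub-assembly and
    greedy overlap-layout-consensus merging, circular genome detection by
    terminal-repeat collapse, six-frame translated homology search with
    Karlin-Altschul E-values and virus/non-virus best-hit arbitration,
    degenerate protein motif scanning for parvovirus NS1/VP1 and
    polyomavirus large T antigen hallmarks, ICTV-style species demarcation
    by pairwise protein identity, and neighbor-joining trees from identity
    distance matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    S4Vectors,
    ape,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
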