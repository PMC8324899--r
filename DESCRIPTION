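Package: spacerlink
Title: CRISPR Spacer-Based Virus-Host Linkage for Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts virus-host linkages in metagenomes from CRISPR
    immunity records. Mines spacers from raw reads anchored on exact
    direct-repeat matches, collapses them into identity clusters, matches
    cluster representatives to candidate scaffolds with a short-query
    seeded local aligner, classifies spacer-targeted scaffolds into
    viruses and putative viruses (length gate, terminal-repeat
    circularity, hallmark-gene evidence, mini-CRISPR screening), and
    tracks normalized coverages, host-virus ratios and spacer
    diversification across timepoints. Ships a fully deterministic
    synthetic subsurface-community generator (host with an evolving
    CRISPR array, protospacer-bearing viruses, background genomes,
    shotgun reads) so every stage is testable against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    BiocGenerics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
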