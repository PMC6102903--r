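Package: phageome
Title: Read- and Assembly-Based Taxonomic and Functional Profiling of
    Phageomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A modular toolkit for shotgun metagenomic analysis of viral
    communities (phageomes). Implements iterative multi-database read
    classification with viral-first priority, ORF-vote taxonomic
    classification of assembled contigs, cross-sample contaminant ("kitome")
    detection with 99-percent-identity read scrubbing, mother-infant phage
    transmission detection by stringent read mapping, rarefaction-based
    sequencing-depth sizing with logarithmic trend fitting, best-hit
    functional profiling, CRISPR-spacer host prediction, and marker-module
    screening for novel (pro)phage contigs. A deterministic built-in
    seed-and-extend local aligner provides the homology engine; seeded
    synthetic-community generators provide fully specified test fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    igraph,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
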