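Package: fl16s
Title: Full-Length 16S rRNA Circular-Consensus Microbiome Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Profiling of microbial communities from full-length 16S rRNA
    (V1-V9) circular consensus sequencing (CCS) reads. Implements the
    pre-clustering read filters (pass count, length, expected error, host
    k-mer screen, degenerate-primer matching and orientation), greedy
    centroid OTU clustering at 97% identity with de novo and
    reference-based two-parent chimera detection, a k-mer bootstrap
    taxonomic classifier with per-rank confidence values over a
    species-level utax-dialect database, database-OTU (dbOTU) average
    linkage clustering and nearly-best-hit cross-referencing, amplicon
    sequence variant detection by minimum entropy decomposition, copy
    number aware expected abundances with binomial detection
    probabilities, community diversity summaries, and a mock community
    read simulator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
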