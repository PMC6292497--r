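Package: chordcomp
Title: Comparative Transcriptomics and Regulatory Genomics of Chordates
Version: 0.1.0
Authors@R: person("chordcomp", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for comparative analysis of chordate functional genomics
    data between an invertebrate outgroup (such as amphioxus) and
    vertebrates: Jensen-Shannon transcriptome divergence across
    developmental stages with bootstrap dispersion (hourglass testing),
    neighbourhood analysis of conserved co-expression (NACC), cross-species
    co-expression module comparison via hypergeometric tests and motif
    z-score correlations, GREAT-style regulatory-domain construction and
    peak-to-gene assignment, ATAC-seq peak classification, CpG methylation
    summarisation and two-cluster separation of regulatory elements, and
    classification of post-whole-genome-duplication paralogue expression
    fates (redundancy, subfunctionalization, specialization). A synthetic
    data generator with recorded ground truth makes every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
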