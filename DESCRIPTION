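Package: pirnascape
Title: piRNA Cluster Calling, piRNA Sequence Signatures, and Transposon
    Activity Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for germline small-RNA sequencing and
    transposable-element (TE) population data. Implements a three-stage
    seed/core/cluster piRNA-cluster-calling algorithm that incorporates
    uniquely mapping, primary multimapping and secondary multimapping
    alignments in a stepwise manner; piRNA sequence-signature statistics
    (length spectra, positional 1U/10A base frequencies, ping-pong overlap
    z-scores and phasing distance histograms); TE transpositional-activity
    statistics from biallelic insertion allele frequencies (within- and
    between-population TE diversity and their ratio ranking); permutation
    and bootstrap tests for interval enrichment of clusters in genome
    annotations; motif scanning with mismatches; and synthetic-data
    generators with known ground truth against which every stage is
    validated.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    Biostrings,
    methods,
    tools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
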