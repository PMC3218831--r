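Package: spliceq
Title: Splice-Junction Read Counting and Differential Analysis for RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A back-end toolkit for bulk RNA-Seq gene expression and RNA
    processing analysis. Builds exhaustive splice-junction contig libraries
    from transcript annotation (every forward donor-acceptor combination per
    gene), selects unique-best read placements across genome and junction
    alignment spaces, counts reads for gene models and two-isoform RNA
    processing events (cassette exons, retained introns, alternative terminal
    exons), and tests for changes with a binomial sampling model whose
    effective library sizes are estimated by minimize-significant-changes
    confidence-interval window voting. Includes Fisher/chi-squared event
    tests, paired-end and read-type quality control summaries,
    cross-experiment comparison utilities, and a deterministic synthetic-data
    generator used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    methods,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
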