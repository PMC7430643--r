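Package: nanotx
Title: Isoform Discovery, Polyadenylation and Modification Profiling for
    Nanopore Direct RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for spliced long-read alignments from native
    (direct) RNA sequencing. Clusters reads into transcript isoforms with
    per-sample quantification, classifies novel isoforms into eleven
    categories and readthrough/fusion transcripts into six structural types,
    calls and matches alternative polyadenylation sites with upstream
    hexamer-motif enrichment, calls differentially expressed genes and
    isoforms between two tissues, and builds normalized metagene profiles of
    per-site RNA modification fractions to compare gene sets. Includes a
    fully deterministic synthetic-data generator (genome, annotation,
    reads, poly(A) tables, modification tables) with planted ground truth
    so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    edgeR,
    jsonlite
Config/testthat/edition: 3
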