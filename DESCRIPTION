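Package: graphsv
Title: Complex Structural Variant Discovery by Signal-Graph Pattern Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects complex structural variants (CSVs) from paired-end
    short-read alignments. Abnormal alignments (clipped reads, split reads,
    discordant read pairs) are clustered into weighted signal nodes and
    connected by paired and reference-adjacency edges to form a signal
    graph; CSVs are reported as maximal subgraphs found by a bottom-up
    pattern-growth search, with a complexity score and edge-derived type
    labels. Includes a two-tier benchmark evaluator (unique-interval and
    all-breakpoint match) and a self-contained diploid rearrangement
    simulator with a truth-guided aligner, so the whole method can be
    exercised without external data or aligners.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rsamtools,
    Biostrings,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    igraph,
    optparse
Config/testthat/edition: 3
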