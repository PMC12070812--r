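Package: pirnasig
Title: piRNA Signature and Transposon Silencing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of small-RNA sequencing libraries mapped to consensus
    transposable elements (TEs): 3' trimming and read collapsing, exact-match
    alignment to both strands of a consensus TE panel with multi-mapper
    apportioning, ping-pong (Z10) and phasing (Z0) signature statistics,
    1U/10A nucleotide biases, piRNAs-per-kilobase quantification,
    median-of-ratios normalization and differential expression with
    Benjamini-Hochberg correction, genetic-interaction (GI) scores for double
    mutants, length-by-expression quadrant analysis of de-silenced TEs,
    concomitant sense/antisense reduction grouping, and PIWI-clade IP group
    assignment. Includes a synthetic ovary-library generator with ground
    truth so the whole stack is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
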