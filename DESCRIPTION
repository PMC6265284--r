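Package: natlnc
Title: Identification and Neighbor Co-Expression Analysis of Long Non-Coding
    RNAs and Natural Antisense Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for annotating long non-coding RNAs (lncRNAs)
    from an assembled transcriptome: a stringent filtering cascade (assembler
    class codes, length and abundance, protein-homology and coding-potential
    filters, sense-overlap removal), a strand-aware classifier of natural
    antisense transcript (NAT) subtypes versus lincRNAs with a brute-force
    oracle, FPKM-based fraction-enrichment and differential-expression calls,
    neighbor-pair Pearson co-expression with one-tailed Mann-Whitney category
    comparisons, and small-RNA quality checks. Includes a synthetic-data
    generator that plants ground-truth lncRNA classes, pair correlations,
    fraction enrichments and coding-potential decoys so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
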