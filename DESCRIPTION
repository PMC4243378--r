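Package: enhmap
Title: Consensus Binding-Interval Mapping and Enhanceosome Module Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated analysis toolkit for transcription-factor
    co-occupancy mapping built around the CIITA/RFX5 enhanceosome.
    Derives replicate-consensus binding intervals (BIs) from per-sample
    ChIP-seq peak calls, classifies enhanceosome (CE) marks and data
    coincidence scores, annotates BIs to genes by TSS distance, scores
    ordered RFX5-CREB-NF-Y tri-motif modules with MATCH-style PWM
    similarity, tests rank-based (eCDF) enrichment of differentially
    expressed genes, quantifies allele-specific binding at heterozygous
    SNPs, and integrates a simplified eQTL association with binding
    evidence. Ships a synthetic-data generator with serialized ground
    truth so every stage can be exercised end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    Rsamtools,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
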