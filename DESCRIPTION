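Package: secistrome
Title: Comparative Super-Enhancer Analysis of Master Transcription Factor
    Cistromes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calls super-enhancers (SEs) from ranked enhancer coverage by the
    classic stitch-and-tangent (slope-1) rule, quantifies peak-summit RPKM from
    coverage tracks, scans position weight matrices for motif landscapes and
    known-motif enrichment, compares two cistromes of one master transcription
    factor (constituent classification, TF co-occupancy correlation, co-binding
    fractions, shared-SE constituent breakdown and motif composition), annotates
    SEs to genes and classifies gene expression by a replicate-aware 2-fold
    rule. Ships a seeded synthetic-data generator that plants a two-cell-line
    SE landscape with ground truth so the whole pipeline is testable end to
    end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils,
    tools,
    methods
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
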