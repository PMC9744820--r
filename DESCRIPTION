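Package: peacseq
Title: Off-Target and Translocation Calling for Tag-Insertion Enrichment
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies CRISPR on- and off-target cut sites from anchored-PCR
    enrichment libraries in which a prime-editor-inserted tag marks the edited
    loci. Implements UMI-based deduplication, primer-extension verification to
    remove random-priming artifacts, cut-site clustering, the three candidate
    filters (wild-type background, bidirectional extension-verified support,
    strand orientation), RPM-based enrichment scoring, spacer-PAM mismatch
    search, per-position mismatch profiling with primer-binding-site
    annotation, and detection, classification (five join models) and scoring
    of DNA translocation junctions from split reads. A synthetic-library
    simulator with a ground-truth ledger makes the whole pipeline testable
    without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    rtracklayer,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
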