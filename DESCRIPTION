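Package: agotron
Title: Discovery and Characterization of Argonaute-Bound Short Introns from HITS-CLIP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for identifying agotrons (short, structured,
    GC-rich introns bound by Argonaute as full-length species) in HITS-CLIP
    short-read libraries. Reads are adapter-trimmed, length-filtered and
    assigned to a universe of short annotated regions (40-150 nt introns,
    pre-miRNA and snoRNA loci) allowing one mismatch; per-region read metrics
    (read count, RPM, median read length, fraction of 5'-end aligned reads)
    feed a threshold-based per-dataset classification and a cross-dataset
    consensus call. Called agotrons are characterized physically (GC content,
    folding energy per nucleotide via a built-in base-pair maximization proxy
    or an external MFE tool) and evolutionarily (mean conservation), and their
    5' arm drives a microRNA-style seed-match target analysis (8mer, 7mer-m8,
    7mer-1A, sliding and unconstrained windows) over 3'-UTR sequences with
    expression fold-change stratification and RIP enrichment statistics. A
    seeded synthetic-data module generates every input with planted ground
    truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    GenomicRanges,
    jsonlite,
    Rcpp,
    rtracklayer,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
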