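Package: chromenrich
Title: Consensus Peak Filtering, Matched Random-Fragment Enrichment and
    Single-Cell Relative-Accessibility Analysis for Euchromatic
    Chromatin-Remodeller Binding Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the bespoke computational steps of chromatin
    profiling studies of euchromatin-bound remodellers: cross-replicate
    consensus peak filtering with blacklist and high-background exclusion;
    a matched-size random-fragment null with exact Fisher testing and
    conditional-MLE odds ratios for feature-overlap enrichment;
    putative G-quadruplex (PQS) motif scanning on both strands;
    per-100-million-read and spike-in (ChIP-Rx) coverage normalization;
    expression-stratified metagene and TSS profiling; and single-cell
    ATAC/RNA relative-activity analysis that detects a stochastically
    silenced cell subpopulation. A synthetic-data module generates every
    input with planted ground truth so all stages are testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
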