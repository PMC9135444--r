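Package: cernapipe
Title: Long Non-Coding RNA Discovery and ceRNA Network Construction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline from assembled transcript models and
    expression tables to a competing-endogenous-RNA (lncRNA-miRNA-mRNA)
    regulatory network. Covers long non-coding RNA candidate filtering,
    coding-potential scoring and genomic classification (intergenic,
    antisense, sense, intronic, bidirectional); differential expression
    with fixed fold-change and p-value screens; cis target prediction by
    genomic proximity and trans target prediction by RNA-RNA duplex free
    energy under a nearest-neighbour stacking model; miRNA precursor
    detection (exact mature match plus stem-loop check) and plant-style
    miRNA target and target-mimic scoring with zone-resolved penalties;
    concordance-filtered ceRNA triple assembly with hub ranking and
    hypergeometric term enrichment. Includes a synthetic-data generator
    that plants a machine-readable ground truth so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    methods,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
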