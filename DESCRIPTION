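Package: carpmiR
Title: Small RNA Sequencing Analysis and miRNA Discovery for Carp Skeletal Muscle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable re-implementation of a small-RNA sequencing analysis
    for common carp (Cyprinus carpio) skeletal muscle: read cleaning and
    collapsing to unique sequences, annotation of rRNA/tRNA/snRNA/snoRNA
    contaminants, exact-match genome mapping over a k-mer index, conserved
    miRNA identification against a mature catalog with isomiR clustering and
    representative selection, novel miRNA prediction by hairpin folding under
    a simplified nearest-neighbor energy model with stem-loop, minimum free
    energy and Dicer cleavage-site criteria, cross-species conservation
    partitioning, and 2^-ddCt qPCR expression profiling with one-way ANOVA.
    Includes a synthetic small-RNA read simulator with planted pre-miRNA
    hairpins and a ground-truth manifest for end-to-end recovery benchmarks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    Rcpp,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
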