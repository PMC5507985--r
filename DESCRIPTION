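Package: mirdeg
Title: Degradation-Bias Screening for miRNA Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how RNA degradation distorts microarray miRNA
    expression profiles and flags likely cross-hybridization artifacts
    among annotated miRNAs. Provides a ground-truth simulator for tissue
    time-course and RNase-control degradation designs, variance-stabilizing
    normalization, detection-based filtering, per-miRNA correlation screens
    against RNA integrity (RIN) and storage time, high- versus low-integrity
    differential expression with Wilcoxon-Mann-Whitney tests and
    Benjamini-Hochberg control, hierarchical clustering (Euclidean distance,
    complete linkage), a rule-based classifier separating
    degradation-resilient, degradation-sensitive, cross-hybridization
    artifact and DNA-background signals, miRBase version-bias summaries, and
    an approximate substring screen for homology between mature miRNA
    sequences and transcript fragments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
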