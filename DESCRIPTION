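Package: ltrmap
Title: Endogenous Retroviral LTR Integration-Site Discovery and
    Transposome Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calls endogenous retroviral long terminal repeat (LTR)
    integration sites from linker-mediated PCR enrichment alignments,
    unifies them into cross-individual transposome maps, classifies
    insertion prevalence and pairwise sharing across populations, annotates
    sites with promoter- and enhancer-distance genes, and overlays bulk
    expression count matrices with a permutation-based contrast. Ships an
    in silico cohort generator that emulates LTR-primer-anchored library
    preparation (blunt junction edge, fragment-length decay tail) so every
    stage is testable against known truth without raw sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    withr,
    yaml
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
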