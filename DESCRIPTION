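Package: chromdyn
Title: Chromatin Accessibility Dynamics, Remodeler Relocation and
    Interactome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies time-course chromatin-accessibility trajectories
    (ATAC-seq consensus loci) into closed-to-open, open-to-closed and
    permanently-open dynamics classes, integrates them with gene-expression
    trajectories through TSS-window peak-to-gene assignment, quantifies
    chromatin-remodeler occupancy relocation between timepoints, and calls
    differential interactors from label-free IP-MS intensity matrices with
    fold-change and t-test thresholds. Includes a fully seeded synthetic-data
    generator with planted ground truth and an end-to-end pipeline with a
    machine-readable run report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Epigenetics, ATACSeq, ChIPSeq, Proteomics, Software
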