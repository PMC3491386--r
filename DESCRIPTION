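Package: ironomics
Title: Multi-Omics Analysis Toolkit for the Diatom Low-Iron Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the computational core of a low-iron multi-omics
    workflow for the oceanic diatom Thalassiosira oceanica: differential
    digital gene expression from two-library EST read counts via the Stekel
    log-likelihood ratio statistic with bootstrap or chi-square null
    calibration, 14N/15N metabolic-labeling proteomics quantification with a
    distinctiveness / target-decoy FDR / ppm filter cascade and median-of-PBC
    protein-group ratios, positional promoter motif screening relative to the
    translation start, sister-clade classification of gene trees for lateral
    gene transfer detection, cylinder-model cell morphometry with unit-cell
    back-calculation, delta-delta-Ct for RT-qPCR, and assembly summary
    statistics. Seeded synthetic-data generators with planted truth make every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    ape,
    phangorn,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
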