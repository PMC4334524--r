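Package: regland
Title: Regulatory Landscape Analysis of Open-Chromatin Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for open-chromatin (ATAC-seq and
    FAIRE-seq) analysis of regulatory regions: strand-aware cut-site
    extraction and coverage tracks, fragment-size distributions with
    nucleosome-periodic mode detection, negative-binomial differential
    accessibility with a batch (assay) covariate, classification of
    region dynamics across a tumor time course (stable versus gradual
    opening, Fisher's omnibus combination, signed-p ranking),
    recovery-curve motif enrichment with normalized enrichment scores
    (NES), transcription-factor footprinting with background
    subtraction, peak-to-gene assignment and preranked GSEA linkage to
    expression data. A synthetic-data generator emulates the
    statistical structure of the real assays so that every stage is
    verifiable offline against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    readr,
    rlang,
    stats,
    utils,
    tools,
    MASS,
    S4Vectors,
    BiocGenerics,
    IRanges,
    Biostrings,
    jsonlite,
    yaml,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr,
    fgsea,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
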