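Package: scdose
Title: Dose-Response Analysis of CRISPRi/a Dosage-Titration Perturb-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for targeted multimodal single-cell CRISPR
    screens that gradually titrate transcription-factor dosage. Assigns cells
    to effector lines and single sgRNAs (hashtag demultiplexing and per-guide
    Gaussian mixture calling), estimates per-guide pseudo-bulk log2 fold
    changes against non-targeting controls with bootstrap standard errors and
    Wilcoxon/Benjamini-Hochberg significance, fits linear, four-parameter
    sigmoid and loess dose-response models to every trans gene with AIC model
    selection and cross-validation, classifies responses
    (unresponsive/linear/nonlinear/non-monotonic), predicts responses on a
    common dosage grid, and runs downstream clustering, annotation
    correlation, gene-set enrichment and cell-type correlation analyses.
    Includes a seeded synthetic-data generator emulating the screen design so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    minpack.lm,
    yaml,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
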