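Package: cardalign
Title: Cross-Species Alignment of Developmental Stages from Single-Cell
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Aligns the developmental stages of one species onto another
    from single-cell RNA-seq time courses. Cells are aggregated into
    pseudo-bulk samples per species, cell type and stage; developmentally
    dynamic genes are detected by cubic polynomial regression on log2
    gestational days; standardized expression trajectories are fitted on a
    common log-time grid and matched by partial (subsequence) dynamic time
    warping, yielding a stage-to-stage correspondence table. Includes
    hypergeometric gene-set overlap tests, a linear-model differential
    expression screen for pseudo-bulk contrasts, and a two-species
    synthetic data generator with known ground-truth time warp for
    validating every step.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    DESeq2,
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
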