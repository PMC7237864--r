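Package: embryostrat
Title: Cell-Type, Lineage, Spatial and Noise Reconstruction of Stereotyped Embryos from Per-Embryo scRNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the cellular makeup of stereotypically developing
    embryos from high-depth per-embryo single-cell RNA-seq. Provides two-step
    depth normalization, rank-gap detection of asymmetrically inherited
    maternal transcripts with exact combinatorial match probabilities,
    recursive cell-type discovery by consensus non-negative matrix
    factorization (SCECTION), lineage-tree reconstruction under the
    cell-count doubling constraint, recovery of embryonic axes by PCA with
    pole-trend rotation, constant-rate RNA velocity, geometry-linked
    expression scores (cadherin contact strength, sister-volume ratios),
    expression-noise and timing-variability statistics with a
    piecewise-linear temporal model, and a synthetic-embryo generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    mclust
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
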