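Package: scTypeAssoc
Title: Cell Type Specificity of Complex Traits from GWAS Gene Statistics and Single-Cell Expression
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps gene-based GWAS association signal onto cell types by
    gene-property regression of gene Z-scores on per-cell-type average
    log expression, conditioned on the dataset-wide average expression.
    Implements a three-step workflow over many single-cell RNA-seq
    datasets without merging them: Bonferroni-corrected marginal scans,
    within-dataset stepwise conditional analysis driven by
    proportional-significance rules, and cross-dataset pairwise
    conditional analysis that groups cell types into independent
    association clusters. Includes per-cell-type profile construction
    from raw single-cell matrices, specificity scores and rank binning,
    cross-dataset similarity and embedding, and synthetic fixtures with
    planted expression programs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    data.table,
    Rtsne
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: SingleCell, GeneExpression, GenomeWideAssociation, Regression, Transcriptomics
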