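#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assayNames rowData rowData<-
#' @importFrom SingleCellExperiment SingleCellExperiment
NULL

## ---------------------------------------------------------------------------
## CellTypeProfile
## ---------------------------------------------------------------------------

#' CellTypeProfile: per-cell-type average log expression with dataset average
#'
#' A `CellTypeProfile` holds the genes x cell-types matrix of per-cell-type
#' mean log2 expression (assay `"E"`), together with the per-gene arithmetic
#' mean of those columns (`rowData` column `"Average"`), the dataset-wide
#' average expression that serves as the conditioning covariate in the
#' gene-property regression. It extends
#' \linkS4class{SummarizedExperiment}, so genes are rows and cell types are
#' columns; subsetting columns with `[` recomputes the average over the
#' retained cell types.
#'
#' @slot .Data inherited \code{SummarizedExperiment} structure; assay
#'   \code{"E"} is the genes x cell-types matrix, \code{rowData()$Average}
#'   the per-gene mean over cell types, and \code{metadata()} carries
#'   \code{datasetId} and \code{species}.
#'
#' @seealso [buildProfile()], [subsetProfile()], [avgExpr()]
#' @export
setClass("CellTypeProfile", contains = "SummarizedExperiment")

.validCellTypeProfile <- function(object) {
    msg <- character()
    if (!"E" %in% assayNames(object))
        msg <- c(msg, "assay 'E' is required")
    else {
        E <- assay(object, "E")
        if (is.null(rownames(E)) || is.null(colnames(E)))
            msg <- c(msg, "assay 'E' must have gene rownames and cell-type colnames")
        else {
            if (anyDuplicated(rownames(E)))
                msg <- c(msg, "gene ids must be unique")
            if (anyDuplicated(colnames(E)))
                msg <- c(msg, "cell-type names must be unique within a dataset")
        }
        if (any(E < 0))
            msg <- c(msg, "expression values must be non-negative")
        if (!"Average" %in% colnames(rowData(object)))
            msg <- c(msg, "rowData column 'Average' is required")
        else {
            avg <- rowData(object)$Average
            dev <- max(abs(avg - rowMeans(E)), 0)
            if (is.na(dev) || dev > 1e-8)
                msg <- c(msg, sprintf(
                    "'Average' must equal the mean of E across cell types (max dev %.3g)", dev))
        }
    }
    md <- metadata(object)
    if (is.null(md$datasetId) || !is.character(md$datasetId))
        msg <- c(msg, "metadata 'datasetId' must be a character scalar")
    if (!is.null(md$species) &&
        !md$species %in% c("human", "mouse", "other"))
        msg <- c(msg, "species must be one of 'human', 'mouse', 'other'")
    if (length(msg)) msg else TRUE
}

setValidity("CellTypeProfile", .validCellTypeProfile)

#' Construct a CellTypeProfile
#'
#' @param E genes x cell-types numeric matrix of per-cell-type mean log2
#'   expression, with gene rownames and cell-type colnames.
#' @param average optional per-gene average over cell types; computed as
#'   `rowMeans(E)` when `NULL`. Must equal that mean (it is the conditioning
#'   covariate, not a free column).
#' @param datasetId identifier of the originating dataset.
#' @param species `"human"`, `"mouse"` or `"other"`.
#'
#' @return A [CellTypeProfile-class] object.
#' @examples
#' E <- matrix(rexp(20), 10, 2,
#'             dimnames = list(paste0("g", 1:10), c("neuron", "glia")))
#' p <- CellTypeProfile(E, datasetId = "toy")
#' avgExpr(p)[1:3]
#' @export
CellTypeProfile <- function(E, average = NULL, datasetId = "dataset",
                            species = c("other", "human", "mouse")) {
    species <- match.arg(species)
    E <- as.matrix(E)
    storage.mode(E) <- "double"
    if (is.null(average)) average <- rowMeans(E)
    se <- SummarizedExperiment(
        assays = list(E = E),
        rowData = DataFrame(Average = unname(average), row.names = rownames(E)))
    metadata(se) <- list(datasetId = datasetId, species = species)
    new("CellTypeProfile", se)
}

## ---------------------------------------------------------------------------
## GeneStats
## ---------------------------------------------------------------------------

#' GeneStats: per-gene association Z-scores with technical covariates
#'
#' Container for gene-based GWAS association statistics: a named Z-score per
#' gene (the probit transform of the gene-based P-value), an optional matrix
#' of technical confounders (e.g. gene length and log gene length), and an
#' optional gene-gene correlation matrix induced by linkage disequilibrium,
#' used for generalized-least-squares fitting.
#'
#' @slot traitId character; trait identifier.
#' @slot z named numeric; per-gene Z-score.
#' @slot confounders numeric matrix, genes x k (possibly zero columns),
#'   rownames matching `names(z)`.
#' @slot geneCorr `NULL` or symmetric positive-semidefinite matrix with unit
#'   diagonal, dimnames matching the genes.
#' @seealso [readGeneStats()], [fitMarginal()], [decorrelate()]
#' @export
setClass("GeneStats", representation(
    traitId = "character",
    z = "numeric",
    confounders = "matrix",
    geneCorr = "ANY"))

.validGeneStats <- function(object) {
    msg <- character()
    z <- object@z
    if (is.null(names(z)) || anyDuplicated(names(z)))
        msg <- c(msg, "z must be named by unique gene ids")
    if (any(!is.finite(z)))
        msg <- c(msg, "z must be finite")
    B <- object@confounders
    if (nrow(B) != length(z) ||
        (length(z) && !identical(rownames(B), names(z))))
        msg <- c(msg, "confounder rows must match genes in z")
    if (ncol(B) > 0) {
        if (is.null(colnames(B)))
            msg <- c(msg, "confounder columns must be named")
        if (any(apply(B, 2, function(x) all(x == 0))))
            msg <- c(msg, "confounders must not contain an all-zero column")
    }
    C <- object@geneCorr
    if (!is.null(C)) {
        if (!is.matrix(C) || nrow(C) != length(z) || ncol(C) != length(z))
            msg <- c(msg, "geneCorr must be a square genes x genes matrix")
        else {
            if (max(abs(C - t(C))) > 1e-8)
                msg <- c(msg, "geneCorr must be symmetric")
            if (max(abs(diag(C) - 1)) > 1e-8)
                msg <- c(msg, "geneCorr must have unit diagonal")
            if (!identical(rownames(C), names(z)))
                msg <- c(msg, "geneCorr dimnames must match genes in z")
        }
    }
    if (length(msg)) msg else TRUE
}

setValidity("GeneStats", .validGeneStats)

#' Construct a GeneStats object
#'
#' @param z named numeric vector of gene-based Z-scores (one per gene).
#' @param confounders optional genes x k matrix of technical confounders;
#'   rows are matched to `names(z)` by rowname when present, otherwise
#'   assumed aligned.
#' @param geneCorr optional genes x genes correlation matrix (LD-induced);
#'   symmetric with unit diagonal.
#' @param traitId trait identifier.
#' @return A [GeneStats-class] object.
#' @examples
#' gs <- GeneStats(setNames(rnorm(5), paste0("g", 1:5)), traitId = "toy")
#' geneZ(gs)
#' @export
GeneStats <- function(z, confounders = NULL, geneCorr = NULL,
                      traitId = "trait") {
    z <- unlist(z)
    if (is.null(confounders)) {
        confounders <- matrix(numeric(), length(z), 0,
                              dimnames = list(names(z), NULL))
    } else {
        confounders <- as.matrix(confounders)
        if (!is.null(rownames(confounders)))
            confounders <- confounders[names(z), , drop = FALSE]
        else
            rownames(confounders) <- names(z)
    }
    if (!is.null(geneCorr)) {
        geneCorr <- as.matrix(geneCorr)
        if (!is.null(rownames(geneCorr)))
            geneCorr <- geneCorr[names(z), names(z), drop = FALSE]
        else
            dimnames(geneCorr) <- list(names(z), names(z))
    }
    new("GeneStats", traitId = traitId, z = z, confounders = confounders,
        geneCorr = geneCorr)
}

## ---------------------------------------------------------------------------
## GeneMapping
## ---------------------------------------------------------------------------

#' GeneMapping: source-to-target gene identifier mapping
#'
#' A two-column gene identifier mapping, either a one-to-one ortholog table
#' (both columns unique, e.g. mouse to human Ensembl) or a symbol/alias
#' table (many aliases may point to the same target).
#'
#' @slot source character; source-namespace gene ids.
#' @slot target character; target-namespace gene ids, parallel to `source`.
#' @slot policy `"one_to_one_ortholog"` or `"symbol_alias"`.
#' @seealso [mapGenes()], [readGeneMapping()]
#' @export
setClass("GeneMapping", representation(
    source = "character", target = "character", policy = "character"))

setValidity("GeneMapping", function(object) {
    msg <- character()
    if (length(object@source) != length(object@target))
        msg <- c(msg, "source and target must have equal length")
    if (!object@policy %in% c("one_to_one_ortholog", "symbol_alias"))
        msg <- c(msg, "policy must be 'one_to_one_ortholog' or 'symbol_alias'")
    if (identical(object@policy, "one_to_one_ortholog")) {
        if (anyDuplicated(object@source) || anyDuplicated(object@target))
            msg <- c(msg,
                "one_to_one_ortholog mapping must be unique in both columns")
    } else if (anyDuplicated(object@source)) {
        msg <- c(msg, "source ids must be unique (aliases may share a target)")
    }
    if (length(msg)) msg else TRUE
})

#' @param source,target parallel character vectors of gene ids.
#' @param policy mapping policy; under `"one_to_one_ortholog"` both columns
#'   must be duplicate-free.
#' @return A [GeneMapping-class] object.
#' @rdname GeneMapping-class
#' @export
GeneMapping <- function(source, target,
                        policy = c("one_to_one_ortholog", "symbol_alias")) {
    new("GeneMapping", source = as.character(source),
        target = as.character(target), policy = match.arg(policy))
}

## ---------------------------------------------------------------------------
## FitResult
## ---------------------------------------------------------------------------

#' FitResult: one gene-property regression fit
#'
#' Result of a single least-squares fit of gene Z-scores on an intercept,
#' one or two cell-type expression columns, the dataset average(s) and the
#' technical confounders. One-sided P-values (upper tail, Student-t with
#' `df = nGenesUsed - nTerms`) are reported for the tested expression
#' term(s) only.
#'
#' @slot termNames character; design column names.
#' @slot beta,se,tStat numeric; per-term estimates (named).
#' @slot pOneSided named numeric; one-sided P per tested expression term
#'   (`NA` when the fit was flagged colinear).
#' @slot df integer; residual degrees of freedom.
#' @slot nGenesUsed integer; genes entering the fit.
#' @slot colinear logical; `TRUE` when the two tested expression columns
#'   were too collinear to separate and P-values were withheld.
#' @export
setClass("FitResult", representation(
    termNames = "character",
    beta = "numeric",
    se = "numeric",
    tStat = "numeric",
    pOneSided = "numeric",
    df = "integer",
    nGenesUsed = "integer",
    colinear = "logical"))

setValidity("FitResult", function(object) {
    msg <- character()
    if (object@df != object@nGenesUsed - length(object@termNames))
        msg <- c(msg, "df must equal nGenesUsed - number of terms")
    p <- object@pOneSided
    if (!object@colinear && length(p) &&
        (any(is.na(p)) || any(p <= 0) || any(p > 1)))
        msg <- c(msg, "one-sided P-values must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Embedding2D
## ---------------------------------------------------------------------------

#' Embedding2D: best-of-restarts 2-D t-SNE embedding
#'
#' @slot coords n x 2 coordinate matrix with entity rownames.
#' @slot klDivergence final Kullback-Leibler divergence of the chosen run.
#' @slot restartIndex 1-based index of the chosen restart (minimal KL).
#' @slot seed master seed the restart sub-seeds were derived from.
#' @slot perplexity perplexity actually used (possibly reduced for small n).
#' @seealso [embedCellTypes()]
#' @export
setClass("Embedding2D", representation(
    coords = "matrix",
    klDivergence = "numeric",
    restartIndex = "integer",
    seed = "integer",
    perplexity = "numeric"))

## ---------------------------------------------------------------------------
## WorkflowSummary
## ---------------------------------------------------------------------------

#' WorkflowSummary: results of the 3-step cell-type association workflow
#'
#' Bundles the per-cell-type marginal scan (step 1), the within-dataset
#' conditional selection (step 2) and the cross-dataset independence
#' clustering (step 3) for one trait, together with the Bonferroni
#' threshold used and the full pairwise logs.
#'
#' @slot traitId trait identifier.
#' @slot threshold Bonferroni-corrected significance threshold of step 1.
#' @slot step1 data.frame: dataset, cell_type, beta, se, t, p, n_genes,
#'   significant.
#' @slot step2Retained data.frame: subset of step-1 rows surviving step 2.
#' @slot step2Pairs data.frame: full within-dataset conditional pair log.
#' @slot step3Clusters data.frame: dataset, cell_type, cluster, founder.
#' @slot step3Pairs data.frame: cross-dataset conditional pair log.
#' @slot counts named integer: n_datasets, step1, step2, step3.
#' @seealso [runWorkflow()]
#' @export
setClass("WorkflowSummary", representation(
    traitId = "character",
    threshold = "numeric",
    step1 = "data.frame",
    step2Retained = "data.frame",
    step2Pairs = "data.frame",
    step3Clusters = "data.frame",
    step3Pairs = "data.frame",
    counts = "integer"))

setValidity("WorkflowSummary", function(object) {
    msg <- character()
    key <- function(df) paste(df$dataset, df$cell_type, sep = "\r")
    s1 <- key(object@step1[object@step1$significant, , drop = FALSE])
    s2 <- key(object@step2Retained)
    s3 <- key(object@step3Clusters)
    if (!all(s2 %in% s1))
        msg <- c(msg, "step-2 retained cell types must be step-1 significant")
    if (!all(s3 %in% s2))
        msg <- c(msg, "step-3 cell types must be step-2 retained")
    if (length(msg)) msg else TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a
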