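#' Accessors for scTypeAssoc classes
#'
#' `exprValues()` returns the genes x cell-types log-average expression
#' matrix of a [CellTypeProfile-class]; `avgExpr()` the named per-gene
#' average over cell types; `cellTypes()` the cell-type names;
#' `datasetId()` and `profileSpecies()` the dataset metadata. For a
#' [GeneStats-class], `geneZ()`, `confounders()`, `geneCorr()` and
#' `traitId()` return the corresponding components.
#'
#' @param x a `CellTypeProfile` or `GeneStats` object.
#' @return The component named by the accessor.
#' @name accessors
#' @aliases exprValues avgExpr datasetId cellTypes profileSpecies geneZ
#'   confounders geneCorr traitId
NULL

#' @rdname accessors
#' @export
setMethod("exprValues", "CellTypeProfile", function(x) assay(x, "E"))

#' @rdname accessors
#' @export
setMethod("avgExpr", "CellTypeProfile", function(x) {
    setNames(rowData(x)$Average, rownames(x))
})

#' @rdname accessors
#' @export
setMethod("datasetId", "CellTypeProfile", function(x) metadata(x)$datasetId)

#' @rdname accessors
#' @export
setMethod("cellTypes", "CellTypeProfile", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("profileSpecies", "CellTypeProfile",
          function(x) metadata(x)$species %||% "other")

#' @rdname accessors
#' @export
setMethod("geneZ", "GeneStats", function(x) x@z)

#' @rdname accessors
#' @export
setMethod("confounders", "GeneStats", function(x) x@confounders)

#' @rdname accessors
#' @export
setMethod("geneCorr", "GeneStats", function(x) x@geneCorr)

#' @rdname accessors
#' @export
setMethod("traitId", "GeneStats", function(x) x@traitId)

## Column subsetting recomputes the Average over the retained cell types:
## the average is defined relative to the cell types in the object, so a
## narrower object conditions on a narrower average (see subsetProfile()).
#' @export
setMethod("[", c("CellTypeProfile", "ANY", "ANY"),
          function(x, i, j, ..., drop = FALSE) {
    out <- callNextMethod(x, i, j, ..., drop = FALSE)
    rowData(out)$Average <- rowMeans(assay(out, "E"))
    validObject(out)
    out
})

setMethod("show", "CellTypeProfile", function(object) {
    cat("CellTypeProfile '", datasetId(object), "' (",
        profileSpecies(object), ")\n", sep = "")
    cat("  ", nrow(object), " genes x ", ncol(object), " cell types\n",
        sep = "")
    ct <- cellTypes(object)
    cat("  cell types: ",
        paste(head(ct, 4), collapse = ", "),
        if (length(ct) > 4) sprintf(", ... (%d more)", length(ct) - 4),
        "\n", sep = "")
    invisible(NULL)
})

setMethod("show", "GeneStats", function(object) {
    cat("GeneStats for trait '", object@traitId, "': ",
        length(object@z), " genes, ", ncol(object@confounders),
        " confounder(s), gene correlation ",
        if (is.null(object@geneCorr)) "absent" else "present", "\n", sep = "")
    invisible(NULL)
})

setMethod("show", "FitResult", function(object) {
    cat("FitResult (", object@nGenesUsed, " genes, df = ", object@df, ")\n",
        sep = "")
    if (object@colinear) {
        cat("  flagged colinear; P-values withheld\n")
    } else {
        for (term in names(object@pOneSided))
            cat(sprintf("  %s: beta = %.4g, se = %.4g, one-sided P = %.3g\n",
                        term, object@beta[term], object@se[term],
                        object@pOneSided[term]))
    }
    invisible(NULL)
})

setMethod("show", "Embedding2D", function(object) {
    cat("Embedding2D: ", nrow(object@coords),
        " entities, KL = ", signif(object@klDivergence, 4),
        " (restart ", object@restartIndex, ", seed ", object@seed, ")\n",
        sep = "")
    invisible(NULL)
})

setMethod("show", "WorkflowSummary", function(object) {
    cnt <- object@counts
    cat("WorkflowSummary for trait '", object@traitId, "'\n", sep = "")
    cat(sprintf("  step 1: %d significant cell types in %d dataset(s) (P < %.3g)\n",
                cnt[["step1"]], cnt[["n_datasets"]], object@threshold))
    cat(sprintf("  step 2: %d retained after within-dataset conditioning\n",
                cnt[["step2"]]))
    cat(sprintf("  step 3: %d independent association cluster(s)\n",
                cnt[["step3"]]))
    invisible(NULL)
})

#' Extract workflow tables
#'
#' @param x a [WorkflowSummary-class].
#' @param name one of `step1`, `step2Retained`, `step2Pairs`,
#'   `step3Clusters`, `step3Pairs`, `threshold`, `counts`, `traitId`.
#' @export
setMethod("$", "WorkflowSummary", function(x, name) slot(x, name))
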