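#' Specificity (S) scores
#'
#' The S score of a gene in a cell type is its expression divided by the
#' sum of its expression over all cell types of the dataset: the
#' proportional expression used by binned-specificity approaches. Rows
#' with all-zero expression get all-zero S.
#'
#' @param profile a [CellTypeProfile-class].
#' @return genes x cell-types matrix; each row with any non-zero
#'   expression sums to 1, and S is 0 wherever E is 0.
#' @examples
#' E <- matrix(c(1, 0, 1, 3, 2, 0), 3, 2,
#'             dimnames = list(paste0("g", 1:3), c("A", "B")))
#' sScore(CellTypeProfile(E))
#' @export
sScore <- function(profile) {
    E <- exprValues(profile)
    tot <- rowSums(E)
    S <- E / ifelse(tot > 0, tot, 1)
    S[tot == 0, ] <- 0
    S
}

#' Equal-count rank binning with zero preservation
#'
#' Ranks values ascending and assigns each to one of `nBins` equal-count
#' bins (`bin = ceiling(rank * nBins / m)` over the `m` binned values).
#' With `zeroPreserved = TRUE` (the default, used for expression averages
#' and S scores), zeros are kept as bin 0 and only positive values are
#' binned, so with `nBins = 100` the output spans 101 possible values
#' (0 to 100), and with `nBins = 40` it spans 41. Ties get their average
#' rank before the ceiling, so the result is deterministic and invariant
#' to input permutation and to strictly monotone transforms.
#'
#' @param values numeric vector; non-negative when `zeroPreserved`.
#' @param nBins positive integer number of bins.
#' @param zeroPreserved keep zeros as bin 0 (default `TRUE`). Use `FALSE`
#'   for signed vectors such as residual specificity, where zero has no
#'   special meaning.
#' @return integer vector of bins, named like `values`.
#' @examples
#' binEqualCount(c(0, 0.5, 1, 2, 8), nBins = 2)
#' @export
binEqualCount <- function(values, nBins, zeroPreserved = TRUE) {
    nBins <- as.integer(nBins)
    if (is.na(nBins) || nBins < 1)
        stop("'nBins' must be a positive integer")
    out <- integer(length(values))
    names(out) <- names(values)
    if (zeroPreserved) {
        if (any(values < 0))
            stop("zero-preserving binning requires non-negative values")
        nz <- values > 0
    } else {
        nz <- rep(TRUE, length(values))
    }
    m <- sum(nz)
    if (m == 0) {
        warning("no values to bin; all assigned bin 0")
        return(out)
    }
    r <- rank(values[nz], ties.method = "average")
    out[nz] <- as.integer(ceiling(r * nBins / m))
    out
}

#' Residual specificity
#'
#' Regresses each cell type's expression column on an intercept and the
#' dataset average, returning the residuals: the part of a cell type's
#' expression not explained by the general expression level of the gene.
#' Used for cross-dataset cell-type comparison.
#'
#' @param profile a [CellTypeProfile-class] with at least 3 genes.
#' @return genes x cell-types matrix of residuals; each column has zero
#'   mean and zero covariance with the average.
#' @export
residualSpecificity <- function(profile) {
    E <- exprValues(profile)
    if (nrow(E) < 3)
        stop("residual specificity needs at least 3 genes")
    A <- avgExpr(profile)
    if (isTRUE(all.equal(stats::var(A), 0)) || stats::var(A) < 1e-300)
        stop("average expression is constant; regression undefined")
    X <- cbind(1, A)
    qr.resid(qr(X), E)
}

#' Top-fraction gene set by score
#'
#' Returns the `ceiling(fraction * n)` genes with the highest scores,
#' e.g. the top-10% cell-type-specific gene sets consumed by
#' SNP-annotation-based enrichment tools. Ties at the boundary are broken
#' by gene id ascending, so the selection is deterministic.
#'
#' @param scores named numeric vector of per-gene scores (>= 10 genes).
#' @param fraction fraction of genes to keep (default 0.10).
#' @return character vector of selected gene ids, highest score first.
#' @export
topDecileGenes <- function(scores, fraction = 0.10) {
    if (length(scores) < 10)
        stop("need at least 10 genes")
    if (is.null(names(scores)))
        stop("'scores' must be named by gene id")
    k <- ceiling(fraction * length(scores))
    ord <- order(-scores, names(scores))
    names(scores)[ord[seq_len(k)]]
}
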