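## Gene-property regression engine.
##
## The model regresses gene-based association Z-scores on the expression of
## a cell type, conditioned on the dataset-wide average expression and
## technical confounders:
##
##   Z = b0 + E_c bE + A bA + B bB + e
##
## with a one-sided test of bE > 0 (positive relation between cell-type
## specific expression and association). Cross-dataset variants add the
## second dataset's average (and, for the conditional model, its cell-type
## expression column). Fitting is ordinary least squares on the qr
## decomposition; when a gene-gene correlation matrix is supplied the whole
## system (response and design, including the intercept) is whitened by the
## inverse Cholesky factor, so OLS on the whitened system is exact GLS.

.collinearityStop <- function(cols) {
    stop(structure(
        class = c("collinearityError", "error", "condition"),
        list(message = paste0("collinear design column(s): ",
                              paste(cols, collapse = ", ")),
             call = sys.call(-1))))
}

.choleskyWhitener <- function(C, ridge = 1e-6) {
    R <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(R))  # ridge only when needed, so an identity stays exact
        R <- tryCatch(chol(C + diag(ridge, nrow(C))), error = function(e)
            stop("gene correlation matrix is not positive definite after ",
                 "ridge ", ridge))
    t(R)  # lower-triangular L with C = L L'
}

## Core fit. `testTerms` are the design columns whose one-sided P is
## reported. `guardPair` (two column names) marks the pair of cell-type
## expression columns whose near-collinearity is flagged rather than
## raised: the fit returns colinear = TRUE with P-values withheld.
.gpFit <- function(z, X, testTerms, geneCorr = NULL, guardPair = NULL,
                   collinearityLimit = 0.999) {
    n <- length(z)
    k <- ncol(X)
    cn <- colnames(X)
    if (!is.null(geneCorr)) {
        L <- .choleskyWhitener(geneCorr)
        z <- forwardsolve(L, z)
        X <- forwardsolve(L, X)
        colnames(X) <- cn
    }
    colinearResult <- function() {
        nam <- rep(NA_real_, k)
        names(nam) <- cn
        new("FitResult", termNames = cn, beta = nam, se = nam, tStat = nam,
            pOneSided = setNames(rep(NA_real_, length(testTerms)), testTerms),
            df = as.integer(n - k), nGenesUsed = as.integer(n),
            colinear = TRUE)
    }
    ## column-equilibrate so rank detection and the guard are insensitive
    ## to covariate scale (gene length is ~1e4 x larger than expression)
    nrm <- sqrt(colSums(X^2))
    if (any(nrm == 0))
        .collinearityStop(cn[nrm == 0])
    X <- sweep(X, 2, nrm, "/")
    qx <- qr(X)
    if (qx$rank < k) {
        dep <- cn[qx$pivot[seq(qx$rank + 1L, k)]]
        if (!is.null(guardPair) && any(guardPair %in% dep))
            return(colinearResult())
        .collinearityStop(dep)
    }
    if (!is.null(guardPair)) {
        others <- setdiff(cn, guardPair)
        q0 <- qr(X[, others, drop = FALSE])
        r1 <- qr.resid(q0, X[, guardPair[1]])
        r2 <- qr.resid(q0, X[, guardPair[2]])
        s1 <- sqrt(sum(r1^2)); s2 <- sqrt(sum(r2^2))
        if (s1 == 0 || s2 == 0 ||
            abs(sum(r1 * r2) / (s1 * s2)) > collinearityLimit)
            return(colinearResult())
    }
    beta <- qr.coef(qx, z)
    res <- qr.resid(qx, z)
    df <- n - k
    sigma2 <- sum(res^2) / df
    covp <- chol2inv(qr.R(qx))
    vb <- numeric(k)
    vb[qx$pivot] <- diag(covp)
    se <- sqrt(sigma2 * vb) / nrm
    names(se) <- cn
    beta <- beta[cn] / nrm
    tstat <- beta / se
    p <- stats::pt(tstat[testTerms], df = df, lower.tail = FALSE)
    new("FitResult", termNames = cn, beta = beta, se = se, tStat = tstat,
        pOneSided = setNames(pmax(p, 1e-300), testTerms),
        df = as.integer(df), nGenesUsed = as.integer(n), colinear = FALSE)
}

.fitGenes <- function(stats, profiles, genes = NULL, minGenes = 50) {
    g <- names(geneZ(stats))
    for (p in profiles) g <- intersect(g, rownames(p))
    if (!is.null(genes)) g <- intersect(g, genes)
    if (length(g) < minGenes)
        stop("only ", length(g), " genes in the intersection (need >= ",
             minGenes, ")")
    g
}

.designBlocks <- function(stats, g) {
    B <- confounders(stats)[g, , drop = FALSE]
    C <- geneCorr(stats)
    if (!is.null(C)) C <- C[g, g, drop = FALSE]
    list(z = geneZ(stats)[g], B = B, C = C)
}

#' Convert gene-based P-values to Z-scores
#'
#' Probit (upper-tail standard-normal quantile) transform: smaller
#' P-values map to larger Z. Values at or below 1e-300 and at or above
#' 1 - 1e-16 are clipped with a warning.
#'
#' @param p numeric vector of P-values in (0, 1); values in \[0, 1\] are
#'   clipped, values outside are an error.
#' @return numeric vector of Z-scores, names preserved.
#' @examples
#' zFromP(c(0.5, 0.025, 0.975))
#' @export
zFromP <- function(p) {
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
        stop("P-values must lie in [0, 1]")
    lo <- p < 1e-300
    hi <- p > 1 - 1e-16
    if (any(lo) || any(hi))
        warning(sum(lo) + sum(hi), " P-value(s) clipped to (1e-300, 1-1e-16)")
    p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
    stats::qnorm(p, lower.tail = FALSE)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param nTests number of dataset-cell-type tests performed.
#' @return `alpha / nTests`.
#' @examples
#' signif(bonferroniThreshold(0.05, 2679), 3)
#' @export
bonferroniThreshold <- function(alpha = 0.05, nTests) alpha / nTests

#' Marginal gene-property fit for one cell type
#'
#' Least-squares fit of the gene Z-scores on an intercept, the cell
#' type's log-average expression, the dataset average, and the technical
#' confounders, over the genes shared by the statistics and the profile.
#' Reports the one-sided (upper-tail, Student-t) P-value for the
#' expression coefficient. When the statistics carry a gene-gene
#' correlation matrix, the fit is generalized least squares via Cholesky
#' whitening.
#'
#' @param stats a [GeneStats-class].
#' @param profile a [CellTypeProfile-class].
#' @param cellType cell-type name to test.
#' @param genes optional gene subset to restrict the fit to.
#' @param minGenes minimum intersection size (default 50).
#' @return A [FitResult-class]; the tested term is `E_<cellType>`.
#' @seealso [fitJointWithin()], [fitCDMarginal()], [fitCDConditional()]
#' @export
fitMarginal <- function(stats, profile, cellType, genes = NULL,
                        minGenes = 50) {
    stopifnot(cellType %in% cellTypes(profile))
    g <- .fitGenes(stats, list(profile), genes, minGenes)
    blk <- .designBlocks(stats, g)
    X <- cbind(1, exprValues(profile)[g, cellType], avgExpr(profile)[g],
               blk$B)
    colnames(X) <- c("(Intercept)", paste0("E_", cellType), "Average",
                     colnames(blk$B))
    .gpFit(blk$z, X, testTerms = paste0("E_", cellType), geneCorr = blk$C)
}

#' Within-dataset joint (conditional) fit for a pair of cell types
#'
#' Single fit of Z on intercept + E_a + E_b + Average + confounders; the
#' one-sided P for each expression term is that cell type's conditional
#' P-value given the other. When the two expression columns are
#' near-collinear after residualizing on the remaining covariates
#' (|correlation| above `collinearityLimit`) or rank-deficient, the pair
#' is flagged colinear and P-values are withheld.
#'
#' @inheritParams fitMarginal
#' @param ctA,ctB two distinct cell types of `profile`.
#' @param collinearityLimit residualized-correlation threshold above
#'   which the pair is flagged (default 0.999).
#' @return A [FitResult-class] with tested terms `E_<ctA>` and `E_<ctB>`
#'   (conditional P-values a|b and b|a).
#' @export
fitJointWithin <- function(stats, profile, ctA, ctB, genes = NULL,
                           minGenes = 50, collinearityLimit = 0.999) {
    stopifnot(ctA %in% cellTypes(profile), ctB %in% cellTypes(profile),
              ctA != ctB)
    g <- .fitGenes(stats, list(profile), genes, minGenes)
    blk <- .designBlocks(stats, g)
    E <- exprValues(profile)
    ta <- paste0("E_", ctA); tb <- paste0("E_", ctB)
    X <- cbind(1, E[g, ctA], E[g, ctB], avgExpr(profile)[g], blk$B)
    colnames(X) <- c("(Intercept)", ta, tb, "Average", colnames(blk$B))
    .gpFit(blk$z, X, testTerms = c(ta, tb), geneCorr = blk$C,
           guardPair = c(ta, tb), collinearityLimit = collinearityLimit)
}

.cdColnames <- function(p1, p2, terms) {
    make.unique(terms, sep = "#")
}

#' Cross-dataset marginal fit
#'
#' Fit of Z on intercept + E_c (from dataset 1) + both datasets' average
#' expression + confounders, over the genes shared by the statistics and
#' both profiles. The one-sided P for the expression term is the
#' cross-dataset (CD) marginal P-value: the association of the cell type
#' after accounting for the general expression of *both* datasets.
#'
#' @inheritParams fitMarginal
#' @param profile1 profile containing `ct`.
#' @param profile2 the other dataset whose average enters the model.
#' @param ct cell type of `profile1` to test.
#' @return A [FitResult-class]; tested term `E_<dataset1>:<ct>`.
#' @export
fitCDMarginal <- function(stats, profile1, ct, profile2, genes = NULL,
                          minGenes = 50) {
    stopifnot(ct %in% cellTypes(profile1))
    g <- .fitGenes(stats, list(profile1, profile2), genes, minGenes)
    blk <- .designBlocks(stats, g)
    te <- paste0("E_", datasetId(profile1), ":", ct)
    cn <- .cdColnames(profile1, profile2, c(
        "(Intercept)", te,
        paste0("Avg_", datasetId(profile1)),
        paste0("Avg_", datasetId(profile2))))
    X <- cbind(1, exprValues(profile1)[g, ct], avgExpr(profile1)[g],
               avgExpr(profile2)[g], blk$B)
    colnames(X) <- c(cn, colnames(blk$B))
    .gpFit(blk$z, X, testTerms = cn[2], geneCorr = blk$C)
}

#' Cross-dataset conditional fit for a pair of cell types
#'
#' Single fit with both cell types' expression columns plus both
#' datasets' averages and the confounders. The one-sided P for each
#' expression term is that cell type's CD conditional P-value given the
#' other dataset's cell type. Near-collinear expression pairs are
#' flagged as in [fitJointWithin()].
#'
#' @inheritParams fitJointWithin
#' @param profile1,profile2 the two datasets.
#' @param ct1,ct2 cell types of `profile1` and `profile2` respectively.
#' @return A [FitResult-class] with both expression terms tested.
#' @export
fitCDConditional <- function(stats, profile1, ct1, profile2, ct2,
                             genes = NULL, minGenes = 50,
                             collinearityLimit = 0.999) {
    stopifnot(ct1 %in% cellTypes(profile1), ct2 %in% cellTypes(profile2))
    g <- .fitGenes(stats, list(profile1, profile2), genes, minGenes)
    blk <- .designBlocks(stats, g)
    cn <- .cdColnames(profile1, profile2, c(
        "(Intercept)",
        paste0("E_", datasetId(profile1), ":", ct1),
        paste0("E_", datasetId(profile2), ":", ct2),
        paste0("Avg_", datasetId(profile1)),
        paste0("Avg_", datasetId(profile2))))
    X <- cbind(1, exprValues(profile1)[g, ct1], exprValues(profile2)[g, ct2],
               avgExpr(profile1)[g], avgExpr(profile2)[g], blk$B)
    colnames(X) <- c(cn, colnames(blk$B))
    .gpFit(blk$z, X, testTerms = cn[2:3], geneCorr = blk$C,
           guardPair = cn[2:3], collinearityLimit = collinearityLimit)
}

#' Whiten gene statistics by the gene-gene correlation
#'
#' Pre-multiplies the Z-scores and the confounder rows by the inverse
#' Cholesky factor of the (ridge-stabilized) gene-gene correlation
#' matrix, so ordinary least squares on the output equals generalized
#' least squares on the input. The fitting functions apply the same
#' whitening internally (to the full design, including intercept and
#' expression columns) whenever `geneCorr` is present; this exported form
#' is for callers who want the transformed statistics themselves.
#'
#' @param stats a [GeneStats-class] with `geneCorr` present.
#' @param ridge diagonal ridge added before the Cholesky factorization
#'   (default 1e-6).
#' @return A [GeneStats-class] with whitened `z` and confounders and no
#'   `geneCorr`.
#' @export
decorrelate <- function(stats, ridge = 1e-6) {
    C <- geneCorr(stats)
    if (is.null(C))
        stop("'stats' has no gene correlation matrix")
    L <- .choleskyWhitener(C, ridge)
    z <- geneZ(stats)
    zt <- setNames(as.vector(forwardsolve(L, z)), names(z))
    B <- confounders(stats)
    if (ncol(B)) {
        Bt <- forwardsolve(L, B)
        dimnames(Bt) <- dimnames(B)
    } else Bt <- B
    GeneStats(zt, Bt, geneCorr = NULL, traitId = traitId(stats))
}
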