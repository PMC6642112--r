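#' Rank-binned Spearman correlation between dataset averages
#'
#' Compares the general expression of two datasets: restricts to shared
#' genes, bins each dataset's average expression into 100 equal-count
#' bins (genes with expression zero are kept as bin 0, so bins span 0 to
#' 100), and computes Spearman's rank correlation of the binned vectors.
#' Binning absorbs dataset-specific scale and distribution (batch)
#' differences; only the rank structure is compared.
#'
#' @param a,b [CellTypeProfile-class] objects sharing >= `minShared` genes.
#' @param nBins bins for the rank transform (default 100).
#' @param minShared minimum shared-gene count (default 30).
#' @return list with `rho` (Spearman correlation) and `nShared`.
#' @export
datasetCorrelation <- function(a, b, nBins = 100, minShared = 30) {
    shared <- intersect(rownames(a), rownames(b))
    if (length(shared) < minShared)
        stop("only ", length(shared), " shared genes (need >= ",
             minShared, ")")
    ba <- binEqualCount(avgExpr(a)[shared], nBins, zeroPreserved = TRUE)
    bb <- binEqualCount(avgExpr(b)[shared], nBins, zeroPreserved = TRUE)
    list(rho = stats::cor(ba, bb, method = "spearman"),
         nShared = length(shared))
}

#' Rank-binned Spearman correlation between two cell types
#'
#' Compares cell-type-specific expression across (or within) datasets:
#' computes residual specificity per dataset (expression regressed on the
#' dataset average), restricts to shared genes, rank-bins each residual
#' vector into 100 bins (no zero carve-out: residual zero has no special
#' meaning), and returns the Spearman correlation.
#'
#' @param a,b [CellTypeProfile-class] objects.
#' @param ctA,ctB cell-type names in `a` and `b` respectively.
#' @inheritParams datasetCorrelation
#' @return list with `rho` and `nShared`.
#' @export
cellTypeCorrelation <- function(a, ctA, b, ctB, nBins = 100,
                                minShared = 30) {
    stopifnot(ctA %in% cellTypes(a), ctB %in% cellTypes(b))
    shared <- intersect(rownames(a), rownames(b))
    if (length(shared) < minShared)
        stop("only ", length(shared), " shared genes (need >= ",
             minShared, ")")
    ra <- residualSpecificity(a)[shared, ctA]
    rb <- residualSpecificity(b)[shared, ctB]
    ba <- binEqualCount(ra, nBins, zeroPreserved = FALSE)
    bb <- binEqualCount(rb, nBins, zeroPreserved = FALSE)
    list(rho = stats::cor(ba, bb, method = "spearman"),
         nShared = length(shared))
}

#' Pairwise similarity matrix over profiles or cell types
#'
#' Assembles the symmetric Spearman correlation matrix over a collection
#' of datasets (average-expression comparison) or over all dataset:cell
#' type combinations (residual-specificity comparison), performing one
#' computation per unordered pair.
#'
#' @param profiles list of [CellTypeProfile-class] objects.
#' @param type `"dataset"` or `"celltype"`.
#' @inheritParams datasetCorrelation
#' @return list with `entities`, symmetric `rho` matrix (unit diagonal),
#'   `nShared` matrix, and a long-format data.frame `pairs`
#'   (entity_a, entity_b, rho, n_shared).
#' @export
pairwiseSimilarity <- function(profiles, type = c("dataset", "celltype"),
                               nBins = 100, minShared = 30) {
    type <- match.arg(type)
    if (type == "dataset") {
        ids <- vapply(profiles, datasetId, character(1))
        feat <- lapply(profiles, function(p)
            binEqualCount(avgExpr(p), nBins, zeroPreserved = TRUE))
    } else {
        ids <- character()
        feat <- list()
        for (p in profiles) {
            res <- residualSpecificity(p)
            for (ct in cellTypes(p)) {
                ids <- c(ids, paste(datasetId(p), ct, sep = ":"))
                feat <- c(feat, list(res[, ct]))
            }
        }
    }
    if (anyDuplicated(ids))
        stop("duplicated entity ids: ", paste(ids[duplicated(ids)],
                                              collapse = ", "))
    k <- length(ids)
    rho <- diag(1, k)
    nsh <- matrix(NA_integer_, k, k)
    dimnames(rho) <- dimnames(nsh) <- list(ids, ids)
    diag(nsh) <- vapply(feat, length, integer(1))
    pairs <- list()
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
        shared <- intersect(names(feat[[i]]), names(feat[[j]]))
        if (length(shared) < minShared)
            stop("only ", length(shared), " shared genes for pair ",
                 ids[i], " / ", ids[j])
        if (type == "dataset") {
            bi <- binEqualCount(feat[[i]][shared], nBins, TRUE)
            bj <- binEqualCount(feat[[j]][shared], nBins, TRUE)
        } else {
            bi <- binEqualCount(feat[[i]][shared], nBins, FALSE)
            bj <- binEqualCount(feat[[j]][shared], nBins, FALSE)
        }
        r <- stats::cor(bi, bj, method = "spearman")
        rho[i, j] <- rho[j, i] <- r
        nsh[i, j] <- nsh[j, i] <- length(shared)
        pairs[[length(pairs) + 1L]] <- data.frame(
            entity_a = ids[i], entity_b = ids[j], rho = r,
            n_shared = length(shared), stringsAsFactors = FALSE)
    }
    list(entities = ids, rho = rho, nShared = nsh,
         pairs = do.call(rbind, pairs))
}

#' Two-sided Mann-Whitney U contrast of two correlation groups
#'
#' Tests whether one group of pairwise correlations is stochastically
#' larger than another (e.g. within-species versus between-species
#' dataset correlations). Exact enumeration is used when both groups have
#' at most 20 values and there are no ties; otherwise the normal
#' approximation with tie correction.
#'
#' @param group1,group2 non-empty numeric vectors.
#' @return two-sided P-value.
#' @export
groupContrast <- function(group1, group2) {
    if (!length(group1) || !length(group2))
        stop("both groups must be non-empty")
    exact <- length(group1) <= 20 && length(group2) <= 20 &&
        !anyDuplicated(c(group1, group2))
    suppressWarnings(
        stats::wilcox.test(group1, group2, alternative = "two.sided",
                           exact = exact, correct = TRUE)$p.value)
}

#' Best-of-restarts 2-D t-SNE embedding
#'
#' Embeds entities (typically dataset:cell-type residual-specificity bin
#' vectors over the common gene intersection) into two dimensions with
#' t-SNE, running the optimisation `restarts` times from distinct
#' sub-seeds and returning the run with the lowest final
#' Kullback-Leibler divergence.
#'
#' @param features entities x features numeric matrix with entity
#'   rownames (>= 4 entities).
#' @param perplexity t-SNE perplexity (default 30); reduced with a
#'   warning when there are fewer than `3 * perplexity + 1` entities.
#' @param restarts number of random restarts (default 100).
#' @param seed master seed; restart sub-seeds are derived from it, so the
#'   result is reproducible.
#' @param ... passed to [Rtsne::Rtsne()].
#' @return An [Embedding2D-class].
#' @export
embedCellTypes <- function(features, perplexity = 30, restarts = 100,
                           seed = 1, ...) {
    features <- as.matrix(features)
    n <- nrow(features)
    if (n < 4)
        stop("need at least 4 entities to embed")
    if (n - 1 < 3 * perplexity) {
        perplexity <- floor((n - 1) / 3)
        warning("perplexity reduced to ", perplexity,
                " for ", n, " entities")
    }
    seed <- as.integer(seed)
    set.seed(seed)
    subseeds <- sample.int(.Machine$integer.max - 1L, restarts)
    best <- NULL
    for (r in seq_len(restarts)) {
        set.seed(subseeds[r])
        fit <- Rtsne::Rtsne(features, dims = 2, perplexity = perplexity,
                            check_duplicates = FALSE, pca = FALSE,
                            theta = if (n < 2000) 0 else 0.5, ...)
        kl <- utils::tail(fit$itercosts, 1)
        if (is.null(best) || kl < best$kl)
            best <- list(kl = kl, coords = fit$Y, restart = r)
    }
    rownames(best$coords) <- rownames(features)
    colnames(best$coords) <- c("x", "y")
    new("Embedding2D", coords = best$coords, klDivergence = best$kl,
        restartIndex = as.integer(best$restart), seed = seed,
        perplexity = perplexity)
}
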