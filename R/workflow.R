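#' Workflow threshold configuration
#'
#' Thresholds driving the pair classification and independence rules:
#' `ps_joint` (below which both conditionals are "jointly explained"),
#' `ps_driver` / `ps_strong` (driver rules), `p_nominal` (nominal
#' conditional significance), `ps_independent` (step-3 mutual
#' independence), and `collinearity` (residualized-correlation limit for
#' flagging pairs).
#'
#' @param ps_joint,ps_driver,ps_strong,p_nominal,ps_independent,collinearity
#'   numeric thresholds; see Description.
#' @return named list of thresholds.
#' @export
psConfig <- function(ps_joint = 0.2, ps_driver = 0.5, ps_strong = 0.8,
                     p_nominal = 0.05, ps_independent = 0.5,
                     collinearity = 0.999) {
    list(ps_joint = ps_joint, ps_driver = ps_driver, ps_strong = ps_strong,
         p_nominal = p_nominal, ps_independent = ps_independent,
         collinearity = collinearity)
}

#' Proportional significance
#'
#' `PS = -log10(p_conditional) / -log10(p_marginal)`: the fraction of a
#' cell type's association (on the log10 scale) that survives
#' conditioning. Near 0 means the association is explained away; near 1
#' means it is unaffected. P-values are floored at 1e-300.
#'
#' @param pMarginal marginal P-value(s), in (0, 1): a marginal P of 1
#'   leaves PS undefined and is an error.
#' @param pConditional conditional P-value(s), in (0, 1].
#' @return numeric PS value(s) >= 0.
#' @examples
#' proportionalSignificance(1e-10, 1e-5)  # 0.5
#' @export
proportionalSignificance <- function(pMarginal, pConditional) {
    if (any(pMarginal <= 0) || any(pConditional <= 0) ||
        any(pConditional > 1))
        stop("P-values must lie in (0, 1]")
    if (any(pMarginal >= 1))
        stop("PS is undefined for a marginal P-value of 1")
    pMarginal <- pmax(pMarginal, 1e-300)
    pConditional <- pmax(pConditional, 1e-300)
    log10(pConditional) / log10(pMarginal)
}

## Scenario table (within-dataset pair classification). Cell type a has
## the smaller marginal P. Scenarios:
##   1 independent          PS_ab >= ps_strong and PS_ba >= ps_strong
##   2 partially joint      PS_ab >= ps_driver and PS_ba >= ps_driver
##   3 jointly explained    PS_ab <  ps_joint  and PS_ba <  ps_joint
##   4 a drives b, residual PS_ab >  ps_strong, PS_ba < ps_driver, p_ba < p_nominal
##   5 a fully drives b     PS_ab >= ps_driver and p_ba >= p_nominal
##   6,7 mirrored 4,5 after the flip rule (b drives a)
##   8 ambiguous            anything else; the stronger marginal is kept
## Flip rule: when PS_ab < ps_joint and PS_ba >= ps_joint, the roles are
## swapped before classification (the nominally weaker cell type may
## explain the stronger one).
.classifyCore <- function(ps1, ps2, p2, cfg) {
    if (ps1 >= cfg$ps_strong && ps2 >= cfg$ps_strong)
        list(scenario = 1L, retain = "both")
    else if (ps1 >= cfg$ps_driver && ps2 >= cfg$ps_driver)
        list(scenario = 2L, retain = "both")
    else if (ps1 < cfg$ps_joint && ps2 < cfg$ps_joint)
        list(scenario = 3L, retain = "first")
    else if (ps1 > cfg$ps_strong && ps2 < cfg$ps_driver && p2 < cfg$p_nominal)
        list(scenario = 4L, retain = "first")
    else if (ps1 >= cfg$ps_driver && p2 >= cfg$p_nominal)
        list(scenario = 5L, retain = "first")
    else
        list(scenario = 8L, retain = "ambiguous")
}

#' Classify a within-dataset conditional pair
#'
#' Applies the proportional-significance decision rules to a pair of
#' Bonferroni-significant cell types from the same dataset, where `a` is
#' the cell type with the smaller marginal P-value. The flip rule is
#' applied first: when PS_ab < 0.2 while PS_ba >= 0.2, the roles are
#' swapped, yielding the mirrored "b drives a" scenarios. Every
#' combination maps to exactly one of eight scenarios.
#'
#' @param pA,pB marginal P-values (`pA <= pB`).
#' @param pAB conditional P of a given b; `pBA` of b given a.
#' @param colinear was the joint fit flagged colinear? If so the pair is
#'   classified `flagged_colinear` and a is retained.
#' @param config a [psConfig()] list.
#' @return one-row data.frame: ps_ab, ps_ba, scenario (1-8 or NA),
#'   action (`retain_both`, `retain_a_drop_b`, `retain_b_drop_a`,
#'   `ambiguous`, `flagged_colinear`), flipped, b_retained.
#' @export
classifyPair <- function(pA, pB, pAB, pBA, colinear = FALSE,
                         config = psConfig()) {
    if (pA > pB)
        stop("'pA' must be the smaller marginal P-value")
    row <- function(ps_ab, ps_ba, scenario, action, flipped) {
        data.frame(p_a = pA, p_b = pB, p_ab = pAB, p_ba = pBA,
                   ps_ab = ps_ab, ps_ba = ps_ba, scenario = scenario,
                   action = action, flipped = flipped,
                   b_retained = action %in% c("retain_both",
                                              "retain_b_drop_a"),
                   stringsAsFactors = FALSE)
    }
    if (colinear)
        return(row(NA_real_, NA_real_, NA_integer_, "flagged_colinear",
                   FALSE))
    ps_ab <- proportionalSignificance(pA, pAB)
    ps_ba <- proportionalSignificance(pB, pBA)
    flipped <- ps_ab < config$ps_joint && ps_ba >= config$ps_joint
    if (!flipped) {
        cls <- .classifyCore(ps_ab, ps_ba, pBA, config)
        action <- switch(cls$retain,
                         both = "retain_both",
                         first = "retain_a_drop_b",
                         ambiguous = "ambiguous")
        row(ps_ab, ps_ba, cls$scenario, action, FALSE)
    } else {
        cls <- .classifyCore(ps_ba, ps_ab, pAB, config)
        scenario <- switch(as.character(cls$scenario),
                           "4" = 6L, "5" = 7L, "8" = 8L, cls$scenario)
        action <- switch(cls$retain,
                         both = "retain_both",
                         first = "retain_b_drop_a",
                         ambiguous = "ambiguous")
        row(ps_ab, ps_ba, scenario, action, TRUE)
    }
}

.profileLookup <- function(profiles) {
    ids <- vapply(profiles, datasetId, character(1))
    if (anyDuplicated(ids))
        stop("profiles must have unique dataset ids")
    setNames(profiles, ids)
}

#' Step 1: Bonferroni-corrected marginal scan
#'
#' Fits the marginal gene-property model for every cell type of every
#' dataset and flags significance at `alpha` Bonferroni-corrected over
#' the total number of dataset-cell-type tests.
#'
#' @param stats a [GeneStats-class].
#' @param profiles list of [CellTypeProfile-class] objects with unique
#'   dataset ids.
#' @param alpha family-wise error rate (default 0.05).
#' @param minGenes minimum gene-intersection size per fit.
#' @return data.frame (dataset, cell_type, beta, se, t, p, n_genes,
#'   significant) with attributes `threshold`, `n_tests`, `alpha`.
#' @export
runStep1 <- function(stats, profiles, alpha = 0.05, minGenes = 50) {
    profiles <- .profileLookup(profiles)
    if (!length(profiles))
        stop("at least one profile is required")
    nTests <- sum(vapply(profiles, ncol, integer(1)))
    threshold <- bonferroniThreshold(alpha, nTests)
    rows <- list()
    for (p in profiles) for (ct in cellTypes(p)) {
        fit <- fitMarginal(stats, p, ct, minGenes = minGenes)
        term <- paste0("E_", ct)
        rows[[length(rows) + 1L]] <- data.frame(
            dataset = datasetId(p), cell_type = ct,
            beta = unname(fit@beta[term]), se = unname(fit@se[term]),
            t = unname(fit@tStat[term]), p = unname(fit@pOneSided[term]),
            n_genes = fit@nGenesUsed, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out$significant <- out$p < threshold
    attr(out, "threshold") <- threshold
    attr(out, "n_tests") <- nTests
    attr(out, "alpha") <- alpha
    out
}

.orderSig <- function(df) df[order(df$p, df$dataset, df$cell_type), ,
                             drop = FALSE]

#' Step 2: within-dataset stepwise conditional selection
#'
#' Per dataset, orders the Bonferroni-significant cell types by marginal
#' P-value and performs forward selection: the strongest cell type seeds
#' the retained list, and each further candidate is classified (via a
#' joint fit and [classifyPair()]) against every retained cell type. The
#' candidate survives only if every pairwise classification retains it.
#' Datasets with a single significant cell type pass it through.
#'
#' @param step1 the [runStep1()] table.
#' @param stats,profiles as in [runStep1()].
#' @param config a [psConfig()] list.
#' @param minGenes minimum gene-intersection size per fit.
#' @return list with `retained` (subset of significant step-1 rows) and
#'   `pairs` (full pair log with scenario, action and PS values).
#' @export
runStep2 <- function(step1, stats, profiles, config = psConfig(),
                     minGenes = 50) {
    profiles <- .profileLookup(profiles)
    sig <- step1[step1$significant, , drop = FALSE]
    retained <- list()
    pairLog <- list()
    for (ds in unique(sig$dataset)) {
        dsig <- .orderSig(sig[sig$dataset == ds, , drop = FALSE])
        keep <- dsig[1, , drop = FALSE]
        if (nrow(dsig) > 1) for (i in seq(2, nrow(dsig))) {
            cand <- dsig[i, , drop = FALSE]
            ok <- TRUE
            for (j in seq_len(nrow(keep))) {
                ret <- keep[j, , drop = FALSE]
                fit <- fitJointWithin(
                    stats, profiles[[ds]], ret$cell_type, cand$cell_type,
                    minGenes = minGenes,
                    collinearityLimit = config$collinearity)
                cls <- classifyPair(
                    pA = ret$p, pB = cand$p,
                    pAB = unname(fit@pOneSided[paste0("E_", ret$cell_type)]),
                    pBA = unname(fit@pOneSided[paste0("E_", cand$cell_type)]),
                    colinear = fit@colinear, config = config)
                pairLog[[length(pairLog) + 1L]] <- cbind(
                    data.frame(dataset = ds, ct_a = ret$cell_type,
                               ct_b = cand$cell_type,
                               stringsAsFactors = FALSE), cls)
                if (!cls$b_retained) ok <- FALSE
            }
            if (ok) keep <- rbind(keep, cand)
        }
        retained[[ds]] <- keep
    }
    pairs <- if (length(pairLog)) do.call(rbind, pairLog) else
        data.frame(dataset = character(), ct_a = character(),
                   ct_b = character(), p_a = numeric(), p_b = numeric(),
                   p_ab = numeric(), p_ba = numeric(), ps_ab = numeric(),
                   ps_ba = numeric(), scenario = integer(),
                   action = character(), flipped = logical(),
                   b_retained = logical(), stringsAsFactors = FALSE)
    ret <- if (length(retained)) do.call(rbind, c(retained,
                                                  make.row.names = FALSE))
           else sig
    list(retained = ret, pairs = pairs)
}

.sharedGenes <- function(stats, p1, p2) {
    intersect(intersect(names(geneZ(stats)), rownames(p1)), rownames(p2))
}

#' Step 3: cross-dataset conditional analysis and independence clusters
#'
#' For every pair of step-2-retained cell types from different datasets,
#' fits the cross-dataset marginal and conditional models and computes
#' the CD proportional significance for both members. Within-dataset
#' pairs reuse the within-dataset joint fit. A pair is mutually
#' independent when both CD PS values exceed `ps_independent` (colinear
#' pairs count as dependent). Forward selection over cell types ordered
#' by step-1 marginal P then groups cell types into independent
#' association clusters: a cell type founds a new cluster iff it is
#' independent of every existing founder, and otherwise joins the first
#' founder that explains it.
#'
#' Each cross-dataset pair also carries `avg_explained` flags: whether
#' adding the other dataset's average expression alone (the CD marginal
#' model) removes at least half of the cell type's step-1 marginal
#' association, with the step-1 fit recomputed on the pair's shared gene
#' set for comparability.
#'
#' @param retained the `retained` table from [runStep2()].
#' @param stats,profiles as in [runStep1()].
#' @param config a [psConfig()] list.
#' @param minGenes minimum gene-intersection size per fit.
#' @return list with `clusters` (dataset, cell_type, p, cluster, founder)
#'   and `pairs` (cross-dataset pair log).
#' @export
runStep3 <- function(retained, stats, profiles, config = psConfig(),
                     minGenes = 50) {
    profiles <- .profileLookup(profiles)
    ret <- .orderSig(retained)
    m <- nrow(ret)
    if (m == 0)
        return(list(clusters = data.frame(dataset = character(),
                                          cell_type = character(),
                                          p = numeric(),
                                          cluster = integer(),
                                          founder = logical()),
                    pairs = NULL))
    indep <- matrix(FALSE, m, m)
    pairLog <- list()
    if (m > 1) for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
        di <- ret$dataset[i]; dj <- ret$dataset[j]
        ci <- ret$cell_type[i]; cj <- ret$cell_type[j]
        if (di == dj) {
            fit <- fitJointWithin(stats, profiles[[di]], ci, cj,
                                  minGenes = minGenes,
                                  collinearityLimit = config$collinearity)
            if (fit@colinear) {
                ok <- FALSE; psi <- psj <- NA_real_
                pci <- pcj <- NA_real_
            } else {
                pci <- unname(fit@pOneSided[paste0("E_", ci)])
                pcj <- unname(fit@pOneSided[paste0("E_", cj)])
                psi <- proportionalSignificance(ret$p[i], pci)
                psj <- proportionalSignificance(ret$p[j], pcj)
                ok <- psi > config$ps_independent &&
                    psj > config$ps_independent
            }
            pairLog[[length(pairLog) + 1L]] <- data.frame(
                dataset_a = di, ct_a = ci, dataset_b = dj, ct_b = cj,
                cd_marginal_p_a = ret$p[i], cd_marginal_p_b = ret$p[j],
                cd_conditional_p_a = pci, cd_conditional_p_b = pcj,
                cd_ps_a = psi, cd_ps_b = psj,
                avg_explained_a = NA, avg_explained_b = NA,
                colinear = fit@colinear, within_dataset = TRUE,
                independent = ok, stringsAsFactors = FALSE)
        } else {
            pi <- profiles[[di]]; pj <- profiles[[dj]]
            g <- .sharedGenes(stats, pi, pj)
            cdmI <- fitCDMarginal(stats, pi, ci, pj, minGenes = minGenes)
            cdmJ <- fitCDMarginal(stats, pj, cj, pi, minGenes = minGenes)
            cdc <- fitCDConditional(stats, pi, ci, pj, cj,
                                    minGenes = minGenes,
                                    collinearityLimit = config$collinearity)
            pmI <- unname(cdmI@pOneSided[1])
            pmJ <- unname(cdmJ@pOneSided[1])
            margI <- fitMarginal(stats, pi, ci, genes = g,
                                 minGenes = minGenes)
            margJ <- fitMarginal(stats, pj, cj, genes = g,
                                 minGenes = minGenes)
            aei <- -log10(pmI) < 0.5 * -log10(unname(margI@pOneSided[1]))
            aej <- -log10(pmJ) < 0.5 * -log10(unname(margJ@pOneSided[1]))
            if (cdc@colinear) {
                ok <- FALSE; psi <- psj <- NA_real_
                pci <- pcj <- NA_real_
            } else {
                pci <- unname(cdc@pOneSided[1])
                pcj <- unname(cdc@pOneSided[2])
                psi <- proportionalSignificance(pmI, pci)
                psj <- proportionalSignificance(pmJ, pcj)
                ok <- psi > config$ps_independent &&
                    psj > config$ps_independent
            }
            pairLog[[length(pairLog) + 1L]] <- data.frame(
                dataset_a = di, ct_a = ci, dataset_b = dj, ct_b = cj,
                cd_marginal_p_a = pmI, cd_marginal_p_b = pmJ,
                cd_conditional_p_a = pci, cd_conditional_p_b = pcj,
                cd_ps_a = psi, cd_ps_b = psj,
                avg_explained_a = aei, avg_explained_b = aej,
                colinear = cdc@colinear, within_dataset = FALSE,
                independent = ok, stringsAsFactors = FALSE)
        }
        if (pairLog[[length(pairLog)]]$independent) {
            indep[i, j] <- indep[j, i] <- TRUE
        }
    }
    cluster <- integer(m)
    founder <- logical(m)
    founders <- integer()
    for (i in seq_len(m)) {
        if (all(indep[i, founders])) {
            founders <- c(founders, i)
            cluster[i] <- length(founders)
            founder[i] <- TRUE
        } else {
            f <- founders[which(!indep[i, founders])[1]]
            cluster[i] <- cluster[f]
        }
    }
    clusters <- data.frame(dataset = ret$dataset, cell_type = ret$cell_type,
                           p = ret$p, cluster = cluster, founder = founder,
                           stringsAsFactors = FALSE)
    pairs <- if (length(pairLog)) do.call(rbind, pairLog) else NULL
    list(clusters = clusters, pairs = pairs)
}

#' Run the full 3-step cell-type association workflow
#'
#' Convenience wrapper chaining [runStep1()], [runStep2()] and
#' [runStep3()] for one trait, returning a [WorkflowSummary-class].
#'
#' @inheritParams runStep1
#' @param config a [psConfig()] list.
#' @return A [WorkflowSummary-class].
#' @examples
#' \dontrun{
#' ws <- runWorkflow(stats, profiles)
#' ws$step3Clusters
#' }
#' @export
runWorkflow <- function(stats, profiles, alpha = 0.05,
                        config = psConfig(), minGenes = 50) {
    step1 <- runStep1(stats, profiles, alpha = alpha, minGenes = minGenes)
    emptyPairs3 <- data.frame(
        dataset_a = character(), ct_a = character(),
        dataset_b = character(), ct_b = character(),
        cd_marginal_p_a = numeric(), cd_marginal_p_b = numeric(),
        cd_conditional_p_a = numeric(), cd_conditional_p_b = numeric(),
        cd_ps_a = numeric(), cd_ps_b = numeric(),
        avg_explained_a = logical(), avg_explained_b = logical(),
        colinear = logical(), within_dataset = logical(),
        independent = logical(), stringsAsFactors = FALSE)
    if (!any(step1$significant)) {
        s2 <- list(retained = step1[step1$significant, , drop = FALSE],
                   pairs = runStep2(step1, stats, profiles, config,
                                    minGenes)$pairs)
        clusters <- data.frame(dataset = character(),
                               cell_type = character(), p = numeric(),
                               cluster = integer(), founder = logical(),
                               stringsAsFactors = FALSE)
        s3pairs <- emptyPairs3
        s2ret <- s2$retained
        s2pairs <- s2$pairs
    } else {
        s2 <- runStep2(step1, stats, profiles, config, minGenes)
        s2ret <- s2$retained
        s2pairs <- s2$pairs
        s3 <- runStep3(s2ret, stats, profiles, config, minGenes)
        clusters <- s3$clusters
        s3pairs <- if (is.null(s3$pairs)) emptyPairs3 else s3$pairs
    }
    counts <- c(
        n_datasets = length(unique(
            step1$dataset[step1$significant])),
        step1 = sum(step1$significant),
        step2 = nrow(s2ret),
        step3 = if (nrow(clusters)) max(clusters$cluster) else 0L)
    new("WorkflowSummary", traitId = traitId(stats),
        threshold = attr(step1, "threshold"), step1 = step1,
        step2Retained = s2ret, step2Pairs = s2pairs,
        step3Clusters = clusters, step3Pairs = s3pairs,
        counts = setNames(as.integer(counts), names(counts)))
}

#' Similarity of cell-type association patterns across traits
#'
#' Spearman correlation of the -log10 marginal P-value vectors of
#' multiple traits over a common dataset:cell-type axis, with
#' average-linkage hierarchical clustering on 1 - rho, and (optionally)
#' the per-trait proportion of significantly associated cell types per
#' annotated category.
#'
#' @param step1List named list of [runStep1()] tables (or
#'   [WorkflowSummary-class] objects), all scanned over the same profile
#'   collection.
#' @param annotation optional data.frame with columns dataset,
#'   cell_type, category mapping each tested cell type to a main
#'   category.
#' @return list with `rho` (trait x trait Spearman matrix), `clustering`
#'   (hclust object), `order` (trait order from the dendrogram),
#'   `proportions` (trait x category matrix of the fraction of each
#'   category's cell types that are significant, or NULL), and
#'   `noSignal` (traits with no significant cell type).
#' @export
traitSimilarity <- function(step1List, annotation = NULL) {
    if (length(step1List) < 2)
        stop("need at least two traits")
    tabs <- lapply(step1List, function(x)
        if (is(x, "WorkflowSummary")) x@step1 else x)
    keys <- lapply(tabs, function(df)
        paste(df$dataset, df$cell_type, sep = ":"))
    ref <- sort(keys[[1]])
    if (!all(vapply(keys, function(k) identical(sort(k), ref), logical(1))))
        stop("traits were not scanned over the same dataset/cell-type axis")
    X <- vapply(tabs, function(df) {
        v <- -log10(df$p)
        v[match(ref, paste(df$dataset, df$cell_type, sep = ":"))]
    }, numeric(length(ref)))
    rho <- stats::cor(X, method = "spearman")
    hc <- stats::hclust(stats::as.dist(1 - rho), method = "average")
    noSignal <- names(tabs)[!vapply(tabs, function(df)
        any(df$significant), logical(1))]
    proportions <- NULL
    if (!is.null(annotation)) {
        akey <- paste(annotation$dataset, annotation$cell_type, sep = ":")
        cat <- annotation$category[match(ref, akey)]
        if (any(is.na(cat)))
            stop("annotation is missing ", sum(is.na(cat)), " cell type(s)")
        cats <- sort(unique(cat))
        proportions <- t(vapply(tabs, function(df) {
            sig <- df$significant[match(ref,
                paste(df$dataset, df$cell_type, sep = ":"))]
            vapply(cats, function(cc) mean(sig[cat == cc]), numeric(1))
        }, numeric(length(cats))))
        colnames(proportions) <- cats
    }
    list(rho = rho, clustering = hc, order = colnames(rho)[hc$order],
         proportions = proportions, noSignal = noSignal)
}
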