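## Synthetic fixtures with planted cell-type expression programs and gene
## statistics that do or do not load on them. Everything is a pure
## function of (spec, seed): program gene sets, expression and gene
## statistics each consume their own seeded RNG stream derived from the
## spec seed, so profiles and statistics can be regenerated independently
## and bit-for-bit.

#' Declare a planted expression program
#'
#' A program is a sparse set of genes over-expressed (by an additive
#' log2-scale shift) in its member cell types, optionally shared across
#' datasets. Programs are what the gene statistics can load on, giving
#' the workflow a known ground truth to recover.
#'
#' @param id program identifier.
#' @param members data.frame with columns `dataset_id`, `cell_type`
#'   naming the cell types carrying the program.
#' @param genes optional integer indices of member genes; when `NULL`,
#'   `round(fraction * nGenes)` genes are sampled at resolution time.
#' @param fraction fraction of genes in the program when sampling
#'   (default 0.05).
#' @param shift additive log2-scale over-expression in member cell types
#'   (default 3, i.e. roughly 8-fold).
#' @return a `plantedProgram` list.
#' @export
plantProgram <- function(id, members, genes = NULL, fraction = 0.05,
                         shift = 3) {
    stopifnot(is.data.frame(members),
              all(c("dataset_id", "cell_type") %in% colnames(members)))
    structure(list(id = id, members = members, genes = genes,
                   fraction = fraction, shift = shift),
              class = "plantedProgram")
}

#' Specify a synthetic fixture
#'
#' @param nGenes number of genes.
#' @param datasets data.frame with columns `dataset_id`, `n_cell_types`,
#'   `cells_per_type`. Cell types are named `ct1`, `ct2`, ...
#' @param programs list of [plantProgram()] declarations.
#' @param causalPrograms optional data.frame with columns `program_id`,
#'   `effect`: programs whose (standardized) gene loading enters the
#'   simulated Z-scores with the given effect size.
#' @param noiseSd per-cell multiplicative log-normal expression noise sd
#'   (natural-log scale; default 0.3).
#' @param batchSd per-dataset gene-level batch effect sd (natural-log
#'   scale; default 0.4): each dataset perturbs the shared baseline by a
#'   gene-wise log-normal factor, emulating protocol differences between
#'   studies. Without it, dataset averages would be nearly identical and
#'   the cross-dataset models degenerate.
#' @param zeroInflation fraction of expression entries set to zero
#'   uniformly at random (default 0).
#' @param zNoiseSd residual sd of the simulated gene Z-scores
#'   (default 1, i.e. null-calibrated noise).
#' @param confounderLeak effect of standardized log gene length on Z
#'   (default 0), to exercise the confounder matrix.
#' @param seed mandatory integer seed; all generators derive from it.
#' @return a validated `fixtureSpec` list.
#' @export
fixtureSpec <- function(nGenes, datasets, programs = list(),
                        causalPrograms = NULL, noiseSd = 0.3,
                        batchSd = 0.4, zeroInflation = 0, zNoiseSd = 1,
                        confounderLeak = 0, seed) {
    if (missing(seed))
        stop("'seed' is mandatory")
    stopifnot(is.data.frame(datasets),
              all(c("dataset_id", "n_cell_types", "cells_per_type") %in%
                  colnames(datasets)),
              !anyDuplicated(datasets$dataset_id),
              nGenes >= 1, zeroInflation >= 0, zeroInflation < 1)
    for (pr in programs) {
        stopifnot(inherits(pr, "plantedProgram"))
        for (r in seq_len(nrow(pr$members))) {
            ds <- pr$members$dataset_id[r]
            i <- match(ds, datasets$dataset_id)
            if (is.na(i))
                stop("program '", pr$id, "' references unknown dataset '",
                     ds, "'")
            valid <- paste0("ct", seq_len(datasets$n_cell_types[i]))
            if (!pr$members$cell_type[r] %in% valid)
                stop("program '", pr$id, "' references unknown cell type '",
                     pr$members$cell_type[r], "' in dataset '", ds, "'")
        }
    }
    if (!is.null(causalPrograms)) {
        stopifnot(all(c("program_id", "effect") %in%
                      colnames(causalPrograms)),
                  all(is.finite(causalPrograms$effect)))
        ids <- vapply(programs, `[[`, character(1), "id")
        if (!all(causalPrograms$program_id %in% ids))
            stop("causal program(s) not declared: ",
                 paste(setdiff(causalPrograms$program_id, ids),
                       collapse = ", "))
    }
    structure(list(nGenes = as.integer(nGenes), datasets = datasets,
                   programs = programs, causalPrograms = causalPrograms,
                   noiseSd = noiseSd, batchSd = batchSd,
                   zeroInflation = zeroInflation, zNoiseSd = zNoiseSd,
                   confounderLeak = confounderLeak,
                   seed = as.integer(seed)),
              class = "fixtureSpec")
}

.geneIds <- function(n) sprintf("g%05d", seq_len(n))

## Resolve sampled program gene sets; deterministic given the spec seed.
.resolvePrograms <- function(spec) {
    set.seed(spec$seed)
    lapply(spec$programs, function(pr) {
        if (is.null(pr$genes))
            pr$genes <- sort(sample.int(spec$nGenes,
                                        max(1, round(pr$fraction *
                                                     spec$nGenes))))
        pr
    })
}

#' Simulate raw expression matrices from a fixture spec
#'
#' Per cell: a gene-level log-normal baseline shared by all cell types,
#' perturbed per dataset by a gene-wise log-normal batch effect, plus the
#' additive log2-scale program shift for the cell's type, plus
#' multiplicative log-normal noise; a `zeroInflation` fraction of entries
#' is then zeroed uniformly at random. Deterministic given the spec seed.
#'
#' @param spec a [fixtureSpec()].
#' @return named list of `SingleCellExperiment` objects (unit `"CPM"`),
#'   one per dataset, as produced by [rawExpression()].
#' @export
simulateProfiles <- function(spec) {
    stopifnot(inherits(spec, "fixtureSpec"))
    programs <- .resolvePrograms(spec)
    gid <- .geneIds(spec$nGenes)
    set.seed(spec$seed)
    baseMean <- stats::rlnorm(spec$nGenes, meanlog = 1, sdlog = 1)
    set.seed(spec$seed + 1L)
    out <- list()
    for (i in seq_len(nrow(spec$datasets))) {
        ds <- spec$datasets$dataset_id[i]
        nct <- spec$datasets$n_cell_types[i]
        k <- spec$datasets$cells_per_type[i]
        cts <- paste0("ct", seq_len(nct))
        shiftMat <- matrix(0, spec$nGenes, nct,
                           dimnames = list(NULL, cts))
        for (pr in programs) {
            mem <- pr$members[pr$members$dataset_id == ds, , drop = FALSE]
            for (ct in mem$cell_type)
                shiftMat[pr$genes, ct] <- shiftMat[pr$genes, ct] + pr$shift
        }
        cells <- matrix(0, spec$nGenes, nct * k)
        labels <- rep(cts, each = k)
        batch <- stats::rnorm(spec$nGenes, 0, spec$batchSd)
        for (c in seq_len(nct)) {
            mu <- log(baseMean) + batch + log(2) * shiftMat[, c]
            idx <- seq((c - 1) * k + 1, c * k)
            cells[, idx] <- exp(mu + stats::rnorm(spec$nGenes * k, 0,
                                                  spec$noiseSd))
        }
        if (spec$zeroInflation > 0) {
            drop <- stats::runif(length(cells)) < spec$zeroInflation
            cells[drop] <- 0
        }
        dimnames(cells) <- list(gid, paste0(ds, "_cell",
                                            seq_len(ncol(cells))))
        out[[ds]] <- rawExpression(cells,
                                   setNames(labels, colnames(cells)),
                                   unit = "CPM")
    }
    out
}

#' Simulate gene statistics loading on planted programs
#'
#' Builds per-gene Z-scores as the sum over causal programs of
#' `effect * standardized loading` plus Gaussian noise, together with
#' simulated gene-length confounders (log-normal length plus its log,
#' with optional leakage into Z). The ground truth (resolved program
#' gene sets, effects, seed) is returned alongside for recovery scoring.
#'
#' @param spec a [fixtureSpec()].
#' @return list with `stats` (a [GeneStats-class]) and `truth` (list of
#'   resolved programs, causal table and seed).
#' @export
simulateGeneStats <- function(spec) {
    stopifnot(inherits(spec, "fixtureSpec"))
    programs <- .resolvePrograms(spec)
    gid <- .geneIds(spec$nGenes)
    set.seed(spec$seed + 2L)
    len <- stats::rlnorm(spec$nGenes, meanlog = log(2e4), sdlog = 1)
    z <- stats::rnorm(spec$nGenes, 0, spec$zNoiseSd)
    if (!is.null(spec$causalPrograms)) {
        for (r in seq_len(nrow(spec$causalPrograms))) {
            prid <- spec$causalPrograms$program_id[r]
            pr <- programs[[which(vapply(programs, `[[`, character(1),
                                         "id") == prid)]]
            lambda <- numeric(spec$nGenes)
            lambda[pr$genes] <- pr$shift
            z <- z + spec$causalPrograms$effect[r] *
                as.vector(scale(lambda))
        }
    }
    if (spec$confounderLeak != 0)
        z <- z + spec$confounderLeak * as.vector(scale(log(len)))
    B <- cbind(LENGTH = len, LOG_LENGTH = log(len))
    rownames(B) <- gid
    stats <- GeneStats(setNames(z, gid), confounders = B,
                       traitId = paste0("sim", spec$seed))
    list(stats = stats,
         truth = list(programs = programs,
                      causal = spec$causalPrograms, seed = spec$seed))
}

#' Expression fixture with mean-coupled specificity
#'
#' Builds a profile in which the specificity of a gene for the first
#' cell type is coupled to the gene's overall expression level with the
#' given coefficient, plus optional mean-dependent dropout (low-mean
#' genes are zeroed more often). This reproduces the confounding
#' mechanism by which binned S scores correlate positively with average
#' expression even when true specificity carries no information --
#' the reason the regression conditions on the dataset average.
#'
#' @param nGenes number of genes.
#' @param coupling coefficient in \[0, 1\]: 0 = specificity independent
#'   of the mean, 1 = fully determined by it.
#' @param nCellTypes number of cell types (default 10).
#' @param zeroInflation overall dropout intensity (default 0); the
#'   per-gene dropout probability decreases with the gene's mean rank.
#' @param seed integer seed.
#' @return A [CellTypeProfile-class].
#' @export
makeConfoundedFixture <- function(nGenes, coupling, nCellTypes = 10,
                                  zeroInflation = 0, seed = 1) {
    stopifnot(coupling >= 0, coupling <= 1)
    set.seed(as.integer(seed))
    m <- stats::rlnorm(nGenes, meanlog = 1, sdlog = 1)
    u <- rank(m, ties.method = "average") / (nGenes + 1)
    eps <- stats::runif(nGenes)
    x <- coupling * stats::qnorm(u) + (1 - coupling) * stats::qnorm(eps)
    W <- matrix(stats::rgamma(nGenes * nCellTypes, shape = 1),
                nGenes, nCellTypes)
    W[, 1] <- exp(x)
    W <- W / rowMeans(W)
    E <- m * W
    if (zeroInflation > 0) {
        pdrop <- pmin(1, 2 * zeroInflation * (1 - u))
        drop <- matrix(stats::runif(length(E)), nGenes, nCellTypes) <
            pdrop
        E[drop] <- 0
    }
    dimnames(E) <- list(.geneIds(nGenes),
                        paste0("ct", seq_len(nCellTypes)))
    CellTypeProfile(E, datasetId = paste0("confounded_c", coupling))
}
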