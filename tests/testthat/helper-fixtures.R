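# Shared fixture builders. Everything is generated in code at test time.

toyProfile <- function(nGenes = 200, nCT = 4, seed = 1,
                       datasetId = "toy", zeroFrac = 0) {
    set.seed(seed)
    E <- matrix(rlnorm(nGenes * nCT, meanlog = 1, sdlog = 1), nGenes, nCT)
    if (zeroFrac > 0)
        E[runif(length(E)) < zeroFrac] <- 0
    dimnames(E) <- list(sprintf("g%05d", seq_len(nGenes)),
                        paste0("ct", seq_len(nCT)))
    CellTypeProfile(E, datasetId = datasetId)
}

toyStats <- function(profile, seed = 99, sd = 1, withB = TRUE) {
    set.seed(seed)
    n <- nrow(profile)
    len <- rlnorm(n, log(2e4), 1)
    B <- if (withB) {
        b <- cbind(LENGTH = len, LOG_LENGTH = log(len))
        rownames(b) <- rownames(profile)
        b
    } else NULL
    GeneStats(setNames(rnorm(n, 0, sd), rownames(profile)),
              confounders = B, traitId = "toytrait")
}

# random positive-definite correlation matrix
randomCorr <- function(n, seed = 1) {
    set.seed(seed)
    A <- matrix(rnorm(n * n), n)
    S <- crossprod(A) + diag(n)
    D <- diag(1 / sqrt(diag(S)))
    C <- D %*% S %*% D
    dimnames(C) <- list(sprintf("g%05d", seq_len(n)),
                        sprintf("g%05d", seq_len(n)))
    (C + t(C)) / 2
}

# brute-force OLS/GLS oracle via normal equations
normalEqOracle <- function(z, X, C = NULL) {
    if (is.null(C)) {
        XtXi <- solve(crossprod(X))
        beta <- XtXi %*% crossprod(X, z)
        res <- z - X %*% beta
        df <- length(z) - ncol(X)
        s2 <- sum(res^2) / df
    } else {
        Ci <- solve(C)
        XtXi <- solve(t(X) %*% Ci %*% X)
        beta <- XtXi %*% t(X) %*% Ci %*% z
        res <- z - X %*% beta
        df <- length(z) - ncol(X)
        s2 <- as.numeric(t(res) %*% Ci %*% res) / df
    }
    se <- sqrt(s2 * diag(XtXi))
    tt <- as.vector(beta) / se
    list(beta = setNames(as.vector(beta), colnames(X)),
         se = setNames(se, colnames(X)),
         t = setNames(tt, colnames(X)),
         p = setNames(pt(tt, df, lower.tail = FALSE), colnames(X)),
         df = df)
}

# simple mean silhouette on a 2-column coordinate matrix
meanSilhouette <- function(coords, labels) {
    d <- as.matrix(dist(coords))
    sil <- vapply(seq_len(nrow(coords)), function(i) {
        a <- mean(d[i, labels == labels[i] & seq_len(nrow(d)) != i])
        b <- min(vapply(setdiff(unique(labels), labels[i]),
                        function(l) mean(d[i, labels == l]), numeric(1)))
        (b - a) / max(a, b)
    }, numeric(1))
    mean(sil)
}

# standard planted-program fixture used by workflow and acceptance tests:
# program P1 in two cell types of d1 (within-dataset duplicate) and one
# cell type each of d2, d3; optionally a second disjoint program P2
# replicated in two further datasets of its own (programs sharing a
# dataset would couple through that dataset's average-expression column).
plantedFixture <- function(seed, nGenes = 1500, twoPrograms = FALSE,
                           effect = 0.4, cellsPerType = 40) {
    ds <- data.frame(dataset_id = c("d1", "d2", "d3"),
                     n_cell_types = c(5, 4, 4),
                     cells_per_type = cellsPerType)
    progs <- list(plantProgram("P1", members = data.frame(
        dataset_id = c("d1", "d1", "d2", "d3"),
        cell_type = c("ct1", "ct2", "ct1", "ct2"))))
    causal <- data.frame(program_id = "P1", effect = effect)
    if (twoPrograms) {
        ds <- rbind(ds, data.frame(dataset_id = c("d4", "d5"),
                                   n_cell_types = 4,
                                   cells_per_type = cellsPerType))
        progs <- c(progs, list(plantProgram("P2", members = data.frame(
            dataset_id = c("d4", "d5"),
            cell_type = c("ct1", "ct2")))))
        causal <- rbind(causal,
                        data.frame(program_id = "P2", effect = effect))
    }
    spec <- fixtureSpec(nGenes = nGenes, datasets = ds, programs = progs,
                        causalPrograms = causal, seed = seed)
    raw <- simulateProfiles(spec)
    profiles <- lapply(names(raw), function(d)
        buildProfile(raw[[d]], datasetId = d))
    sim <- simulateGeneStats(spec)
    list(spec = spec, profiles = profiles, stats = sim$stats,
         truth = sim$truth)
}
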