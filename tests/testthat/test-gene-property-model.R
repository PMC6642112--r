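test_that("zFromP is the upper-tail probit with clipping", {
    expect_equal(zFromP(0.5), 0)
    expect_equal(zFromP(0.025), 1.95996, tolerance = 1e-5)
    expect_equal(zFromP(0.975), -zFromP(0.025))
    expect_warning(z0 <- zFromP(0), "clipped")
    expect_true(is.finite(z0) && z0 > 35)
    expect_error(zFromP(1.2), "0, 1")
    expect_error(zFromP(-0.1), "0, 1")
})

test_that("fitMarginal matches the normal-equations oracle on random instances", {
    for (i in 1:50) {
        p <- toyProfile(nGenes = 200, nCT = 3, seed = 100 + i)
        gs <- toyStats(p, seed = 200 + i)
        fit <- fitMarginal(gs, p, "ct1")
        X <- cbind(1, exprValues(p)[, "ct1"], avgExpr(p),
                   confounders(gs))
        colnames(X) <- fit@termNames
        o <- normalEqOracle(geneZ(gs), X)
        expect_equal(unname(fit@beta), unname(o$beta), tolerance = 1e-8)
        expect_equal(unname(fit@se), unname(o$se), tolerance = 1e-8)
        expect_equal(unname(fit@pOneSided["E_ct1"]),
                     unname(o$p["E_ct1"]), tolerance = 1e-10)
        expect_identical(fit@df, o$df)
    }
})

test_that("a gene correlation matrix turns the fit into exact GLS", {
    for (i in 1:10) {
        p <- toyProfile(nGenes = 80, nCT = 3, seed = 300 + i)
        C <- randomCorr(80, seed = 300 + i)
        gs0 <- toyStats(p, seed = 400 + i)
        gs <- GeneStats(geneZ(gs0), confounders(gs0), geneCorr = C)
        fit <- fitMarginal(gs, p, "ct2")
        X <- cbind(1, exprValues(p)[, "ct2"], avgExpr(p),
                   confounders(gs))
        colnames(X) <- fit@termNames
        o <- normalEqOracle(geneZ(gs), X, C = C)
        expect_equal(unname(fit@beta), unname(o$beta), tolerance = 1e-8)
        expect_equal(unname(fit@se), unname(o$se), tolerance = 1e-8)
    }
})

test_that("decorrelate whitens so OLS cross-products equal GLS normal equations", {
    # identity correlation leaves the statistics untouched
    p <- toyProfile(nGenes = 60, nCT = 2, seed = 1)
    gs0 <- toyStats(p, seed = 2)
    Ci <- diag(60); dimnames(Ci) <- list(rownames(p), rownames(p))
    gsI <- GeneStats(geneZ(gs0), confounders(gs0), geneCorr = Ci)
    w <- decorrelate(gsI)
    expect_equal(geneZ(w), geneZ(gs0))
    expect_equal(confounders(w), confounders(gs0))
    expect_null(geneCorr(w))

    # 2-gene toy with correlation 0.5: hand-computed GLS normal equations
    z <- setNames(c(1.2, -0.4), c("gA", "gB"))
    B <- matrix(c(2, 3), 2, 1, dimnames = list(names(z), "X"))
    C <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(names(z), names(z)))
    w2 <- decorrelate(GeneStats(z, B, geneCorr = C))
    Cinv <- solve(C)
    expect_equal(as.numeric(crossprod(confounders(w2))),
                 as.numeric(t(B) %*% Cinv %*% B), tolerance = 1e-12)
    expect_equal(as.numeric(crossprod(confounders(w2), geneZ(w2))),
                 as.numeric(t(B) %*% Cinv %*% z), tolerance = 1e-12)

    # random 20-gene case: OLS on the whitened output equals the GLS oracle
    C20 <- randomCorr(20, seed = 5)
    set.seed(6)
    z20 <- setNames(rnorm(20), rownames(C20))
    B20 <- matrix(rnorm(40), 20, 2,
                  dimnames = list(names(z20), c("b1", "b2")))
    w20 <- decorrelate(GeneStats(z20, B20, geneCorr = C20))
    bOLS <- solve(crossprod(confounders(w20)),
                  crossprod(confounders(w20), geneZ(w20)))
    o <- normalEqOracle(z20, B20, C = C20)
    expect_equal(as.vector(bOLS), unname(o$beta), tolerance = 1e-8)
    expect_error(decorrelate(toyStats(p)), "no gene correlation")
})

test_that("exact collinearity raises a collinearityError naming the columns", {
    # a single-cell-type profile makes E identical to the average
    E <- matrix(rexp(100), 100, 1,
                dimnames = list(sprintf("g%05d", 1:100), "only"))
    p <- CellTypeProfile(E)
    gs <- toyStats(p)
    err <- expect_error(fitMarginal(gs, p, "only"),
                        class = "collinearityError")
    expect_match(conditionMessage(err), "Average|E_only")
    # a confounder in the span of intercept and average
    p2 <- toyProfile(nGenes = 100, nCT = 3, seed = 9)
    Bspan <- cbind(SPAN = 2 * avgExpr(p2) + 1)
    gs2 <- GeneStats(geneZ(toyStats(p2)), Bspan)
    expect_error(fitMarginal(gs2, p2, "ct1"), class = "collinearityError")
})

test_that("fitJointWithin flags colinear cell-type pairs and withholds P", {
    p <- toyProfile(nGenes = 150, nCT = 3, seed = 10)
    E <- exprValues(p)
    Edup <- cbind(E, dup = E[, "ct1"])
    pdup <- CellTypeProfile(Edup)
    gs <- toyStats(pdup)
    fit <- fitJointWithin(gs, pdup, "ct1", "dup")
    expect_true(fit@colinear)
    expect_true(all(is.na(fit@pOneSided)))
    # near-duplicate triggers the residualized-correlation guard
    Enear <- cbind(E, near = E[, "ct1"] + abs(rnorm(150, 0, 1e-5)))
    pnear <- CellTypeProfile(Enear)
    fitn <- fitJointWithin(toyStats(pnear), pnear, "ct1", "near")
    expect_true(fitn@colinear)
})

test_that("a planted effect is recovered with calibrated significance", {
    p <- toyProfile(nGenes = 2000, nCT = 4, seed = 11)
    gs0 <- toyStats(p, seed = 12)
    X0 <- cbind(1, avgExpr(p), confounders(gs0))
    eres <- qr.resid(qr(X0), exprValues(p)[, "ct1"])
    set.seed(13)
    z <- setNames(0.4 * eres + rnorm(2000), rownames(p))
    gs <- GeneStats(z, confounders(gs0))
    fit <- fitMarginal(gs, p, "ct1")
    expect_lt(abs(fit@beta["E_ct1"] - 0.4), 3 * fit@se["E_ct1"])
    expect_lt(fit@pOneSided["E_ct1"], 1e-4)
})

test_that("conditioning separates a single driver from a correlated bystander", {
    p <- toyProfile(nGenes = 2000, nCT = 4, seed = 14)
    resid <- residualSpecificity(p)
    set.seed(15)
    z <- setNames(0.5 * scale(resid[, "ct1"])[, 1] + rnorm(2000),
                  rownames(p))
    gs <- GeneStats(z)
    fit <- fitJointWithin(gs, p, "ct1", "ct2")
    expect_lt(fit@pOneSided["E_ct1"], 1e-6)
    expect_gt(fit@pOneSided["E_ct2"], 1e-3)
    # null conditional P of the bystander is uniform over replicates
    pb <- vapply(1:60, function(i) {
        set.seed(1000 + i)
        zi <- setNames(0.5 * scale(resid[, "ct1"])[, 1] + rnorm(2000),
                       rownames(p))
        unname(fitJointWithin(GeneStats(zi), p, "ct1",
                              "ct2")@pOneSided["E_ct2"])
    }, numeric(1))
    expect_gt(ks.test(pb, "punif")$p.value, 0.001)
})

test_that("two independent planted drivers both stay conditionally significant", {
    p <- toyProfile(nGenes = 2000, nCT = 4, seed = 16)
    resid <- residualSpecificity(p)
    set.seed(17)
    z <- setNames(0.4 * scale(resid[, "ct1"])[, 1] +
                  0.4 * scale(resid[, "ct3"])[, 1] + rnorm(2000),
                  rownames(p))
    fit <- fitJointWithin(GeneStats(z), p, "ct1", "ct3")
    expect_lt(fit@pOneSided["E_ct1"], 1e-4)
    expect_lt(fit@pOneSided["E_ct3"], 1e-4)
})

test_that("fitCDMarginal rejects identical datasets and ignores orthogonal averages", {
    p1 <- toyProfile(nGenes = 3000, nCT = 3, seed = 18, datasetId = "d1")
    gs0 <- toyStats(p1, seed = 19)
    expect_error(
        fitCDMarginal(gs0, p1, "ct1",
                      CellTypeProfile(exprValues(p1), datasetId = "d2")),
        class = "collinearityError")

    # second dataset whose average is (up to a constant) orthogonal to the
    # whole design and to z: CD marginal equals the plain marginal
    X0 <- cbind(1, avgExpr(p1), confounders(gs0))
    eres <- qr.resid(qr(X0), exprValues(p1)[, "ct1"])
    set.seed(20)
    z <- setNames(0.5 * scale(eres)[, 1] + rnorm(3000), rownames(p1))
    gs <- GeneStats(z, confounders(gs0))
    marg <- fitMarginal(gs, p1, "ct1")
    W <- cbind(1, exprValues(p1)[, "ct1"], avgExpr(p1),
               confounders(gs), z)
    set.seed(21)
    w <- qr.resid(qr(W), rnorm(3000))
    E2 <- matrix(5 + 0.1 * w / sd(w), ncol = 1,
                 dimnames = list(rownames(p1), "other"))
    stopifnot(all(E2 >= 0))
    p2 <- CellTypeProfile(E2, datasetId = "d2")
    cdm <- fitCDMarginal(gs, p1, "ct1", p2)
    expect_equal(unname(cdm@pOneSided[1]), unname(marg@pOneSided[1]),
                 tolerance = 1e-6)
    expect_equal(unname(cdm@beta["E_d1:ct1"]),
                 unname(marg@beta["E_ct1"]), tolerance = 1e-6)
})

test_that("fitCDConditional separates shared from independent cross-dataset programs", {
    fx <- plantedFixture(seed = 22, nGenes = 1200, cellsPerType = 30)
    p1 <- fx$profiles[[1]]; p2 <- fx$profiles[[2]]
    # ct1(d1) and ct1(d2) carry the same causal program
    cdm1 <- fitCDMarginal(fx$stats, p1, "ct1", p2)
    cdm2 <- fitCDMarginal(fx$stats, p2, "ct1", p1)
    cdc <- fitCDConditional(fx$stats, p1, "ct1", p2, "ct1")
    ps1 <- proportionalSignificance(cdm1@pOneSided[1], cdc@pOneSided[1])
    ps2 <- proportionalSignificance(cdm2@pOneSided[1], cdc@pOneSided[2])
    expect_lt(ps1, 0.5)
    expect_lt(ps2, 0.5)
    # colinear cross-dataset pair
    pdup <- CellTypeProfile(exprValues(p1)[, "ct1", drop = FALSE],
                            datasetId = "dup")
    # add a second column so the average is not identical to E
    pdup <- CellTypeProfile(cbind(exprValues(p1)[, "ct1", drop = FALSE],
                                  other = exprValues(p1)[, "ct3"]),
                            datasetId = "dup")
    cdcol <- fitCDConditional(fx$stats, p1, "ct1", pdup, "ct1")
    expect_true(cdcol@colinear)
})

test_that("the gene-intersection floor is enforced and reported", {
    p <- toyProfile(nGenes = 40, nCT = 3)
    gs <- toyStats(p)
    expect_error(fitMarginal(gs, p, "ct1"), "intersection")
    fit <- fitMarginal(gs, p, "ct1", minGenes = 30)
    expect_identical(fit@nGenesUsed, 40L)
})

test_that("null one-sided P-values are uniform", {
    p <- toyProfile(nGenes = 500, nCT = 4, seed = 23)
    pv <- vapply(1:300, function(i) {
        set.seed(2000 + i)
        z <- setNames(rnorm(500), rownames(p))
        unname(fitMarginal(GeneStats(z), p, "ct2")@pOneSided[1])
    }, numeric(1))
    expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})
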