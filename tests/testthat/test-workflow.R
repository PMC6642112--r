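test_that("proportionalSignificance is the -log10 ratio", {
    expect_equal(proportionalSignificance(1e-10, 1e-5), 0.5)
    expect_equal(proportionalSignificance(1e-8, 1e-8), 1)
    expect_equal(proportionalSignificance(1e-8, 1e-2), 0.25)
    expect_error(proportionalSignificance(1, 0.5), "undefined")
    expect_error(proportionalSignificance(1e-5, 0), "0, 1")
})

test_that("classifyPair reproduces the documented scenarios", {
    mk <- function(ps_ab, ps_ba, p_a = 1e-10, p_b = 1e-8)
        classifyPair(p_a, p_b, p_a^ps_ab, p_b^ps_ba)
    r1 <- mk(0.9, 0.9)
    expect_equal(r1$scenario, 1L); expect_equal(r1$action, "retain_both")
    r2 <- mk(0.6, 0.6)
    expect_equal(r2$scenario, 2L); expect_equal(r2$action, "retain_both")
    r3 <- mk(0.1, 0.1)
    expect_equal(r3$scenario, 3L)
    expect_equal(r3$action, "retain_a_drop_b")
    # a drives b but b keeps residual nominal signal
    r4 <- classifyPair(1e-10, 1e-8, 1e-9, 1e-3)  # ps_ab 0.9, ps_ba 0.375
    expect_equal(r4$scenario, 4L)
    expect_equal(r4$action, "retain_a_drop_b")
    # a fully drives b: ps_ab 0.6, p_ba = 0.2 (ps_ba 0.0873)
    r5 <- classifyPair(1e-10, 1e-8, 1e-6, 0.2)
    expect_equal(r5$scenario, 5L)
    expect_equal(r5$action, "retain_a_drop_b")
    # colinear short-circuit
    rc <- classifyPair(1e-10, 1e-8, 1e-9, 1e-7, colinear = TRUE)
    expect_equal(rc$action, "flagged_colinear")
    expect_false(rc$b_retained)
    expect_error(classifyPair(1e-4, 1e-8, 0.1, 0.1), "smaller")
})

test_that("the flip rule yields mirrored b-drives-a scenarios", {
    # PS_ab < 0.2 while PS_ba >= 0.2: b explains a
    # b fully drives a: ps_ba = 0.5, p_ab = 0.1 >= 0.05
    r7 <- classifyPair(1e-10, 1e-8, 10^(-10 * 0.1), 10^(-8 * 0.5))
    expect_true(r7$flipped)
    expect_equal(r7$scenario, 7L)
    expect_equal(r7$action, "retain_b_drop_a")
    expect_true(r7$b_retained)
    r6 <- classifyPair(1e-10, 1e-8, 10^(-10 * 0.15), 10^(-8 * 0.9))
    # flipped, ps_ba 0.9 > 0.8, ps_ab 0.15 < 0.5, p_ab ~ 0.032 < 0.05 -> 6
    expect_true(r6$flipped)
    expect_equal(r6$scenario, 6L)
    expect_equal(r6$action, "retain_b_drop_a")
})

test_that("classifyPair assigns exactly one scenario over an exhaustive grid", {
    psGrid <- seq(0, 1.2, by = 0.1)
    pbGrid <- c(1e-6, 0.04, 0.06, 0.5)
    actions <- c("retain_both", "retain_a_drop_b", "retain_b_drop_a",
                 "ambiguous")
    n <- 0
    for (ps_ab in psGrid) for (ps_ba in psGrid) for (p_b in pbGrid) {
        p_a <- min(p_b, 1e-10)
        res <- classifyPair(p_a, p_b, p_a^ps_ab, p_b^ps_ba)
        expect_true(res$scenario %in% 1:8)
        expect_true(res$action %in% actions)
        # retained set is consistent with the scenario family
        if (res$scenario %in% c(1, 2))
            expect_equal(res$action, "retain_both")
        if (res$scenario %in% c(3, 4, 5))
            expect_equal(res$action, "retain_a_drop_b")
        if (res$scenario %in% c(6, 7))
            expect_equal(res$action, "retain_b_drop_a")
        if (res$flipped)
            expect_true(res$scenario %in% c(6L, 7L, 8L))
        n <- n + 1
    }
    expect_equal(n, length(psGrid)^2 * length(pbGrid))
})

test_that("step 1 applies Bonferroni across all dataset-cell-type tests", {
    expect_equal(signif(bonferroniThreshold(0.05, 2679), 3), 1.87e-5)
    expect_equal(bonferroniThreshold(0.05, 1), 0.05)
    fx <- plantedFixture(seed = 50, nGenes = 1000, cellsPerType = 25)
    s1 <- runStep1(fx$stats, fx$profiles)
    expect_equal(attr(s1, "n_tests"), 13L)  # 5 + 4 + 4 cell types
    expect_equal(attr(s1, "threshold"), 0.05 / 13)
    expect_equal(nrow(s1), 13L)
    planted <- s1$significant[paste(s1$dataset, s1$cell_type) %in%
        c("d1 ct1", "d1 ct2", "d2 ct1", "d3 ct2")]
    expect_true(all(planted))
})

test_that("step 2 deduplicates within-dataset copies and keeps independent signals", {
    fx <- plantedFixture(seed = 51)
    s1 <- runStep1(fx$stats, fx$profiles)
    s2 <- runStep2(s1, fx$stats, fx$profiles)
    # d1 carries the same program in ct1 and ct2: only one survives
    d1 <- s2$retained[s2$retained$dataset == "d1", ]
    expect_equal(nrow(d1), 1L)
    expect_equal(d1$p, min(s1$p[s1$dataset == "d1"]))
    expect_true(all(s2$pairs$scenario %in% c(1:8, NA)))

    # one dataset carrying two disjoint causal programs: both retained
    ds <- data.frame(dataset_id = "dd", n_cell_types = 6,
                     cells_per_type = 40)
    progs <- list(
        plantProgram("Q1", data.frame(dataset_id = "dd",
                                      cell_type = "ct1")),
        plantProgram("Q2", data.frame(dataset_id = "dd",
                                      cell_type = "ct3")))
    spec <- fixtureSpec(1500, ds, progs,
                        causalPrograms = data.frame(
                            program_id = c("Q1", "Q2"), effect = 0.4),
                        seed = 510)
    profs <- list(buildProfile(simulateProfiles(spec)[[1]],
                               datasetId = "dd"))
    st <- simulateGeneStats(spec)$stats
    s1b <- runStep1(st, profs)
    s2b <- runStep2(s1b, st, profs)
    expect_true(all(c("ct1", "ct3") %in% s2b$retained$cell_type))
})

test_that("a single significant cell type passes step 2 unchanged", {
    fx <- plantedFixture(seed = 52)
    s1 <- runStep1(fx$stats, fx$profiles)
    one <- s1[s1$dataset == "d2", ]
    one$significant <- one$cell_type == "ct1"
    s2 <- runStep2(one, fx$stats, fx$profiles)
    expect_equal(nrow(s2$retained), 1L)
    expect_equal(nrow(s2$pairs), 0L)
})

test_that("step 3 groups replicated programs into one cluster and disjoint ones into two", {
    fx <- plantedFixture(seed = 53, twoPrograms = TRUE)
    ws <- runWorkflow(fx$stats, fx$profiles)
    cl <- ws$step3Clusters
    key <- paste(cl$dataset, cl$cell_type)
    p1members <- key %in% c("d1 ct1", "d1 ct2", "d2 ct1", "d3 ct2")
    p2members <- key %in% c("d4 ct1", "d5 ct2")
    expect_equal(length(unique(cl$cluster[p1members])), 1L)
    expect_equal(length(unique(cl$cluster[p2members])), 1L)
    expect_false(any(cl$cluster[p1members] %in% cl$cluster[p2members]))
    expect_equal(ws$counts[["step3"]], 2L)
    # pair log and the asymmetric PS grid are populated
    expect_true(nrow(ws$step3Pairs) > 0)
    grid <- cdPSMatrix(ws)
    expect_true(is.matrix(grid))
    # the step-ordering invariant step3 <= step2 <= step1
    expect_true(all(paste(cl$dataset, cl$cell_type) %in%
        paste(ws$step2Retained$dataset, ws$step2Retained$cell_type)))
    expect_lte(ws$counts[["step3"]], ws$counts[["step2"]])
    expect_lte(ws$counts[["step2"]], ws$counts[["step1"]])
})

test_that("a single retained cell type forms a single cluster", {
    fx <- plantedFixture(seed = 54)
    s1 <- runStep1(fx$stats, fx$profiles)
    keep <- s1[s1$dataset == "d2" & s1$cell_type == "ct1", ]
    s3 <- runStep3(keep, fx$stats, fx$profiles)
    expect_equal(nrow(s3$clusters), 1L)
    expect_true(s3$clusters$founder)
})

test_that("the workflow is deterministic given its inputs", {
    fx <- plantedFixture(seed = 55, nGenes = 1000, cellsPerType = 25)
    ws1 <- runWorkflow(fx$stats, fx$profiles)
    ws2 <- runWorkflow(fx$stats, fx$profiles)
    expect_identical(ws1$step1, ws2$step1)
    expect_identical(ws1$step2Pairs, ws2$step2Pairs)
    expect_identical(ws1$step3Clusters, ws2$step3Clusters)
})

test_that("a null trait produces no discoveries and vacuous later steps", {
    ds <- data.frame(dataset_id = c("n1", "n2"), n_cell_types = 4,
                     cells_per_type = 25)
    spec <- fixtureSpec(nGenes = 800, datasets = ds, seed = 56)
    profiles <- lapply(names(raw <- simulateProfiles(spec)), function(d)
        buildProfile(raw[[d]], datasetId = d))
    ws <- runWorkflow(simulateGeneStats(spec)$stats, profiles)
    expect_equal(ws$counts[["step1"]], 0L)
    expect_equal(ws$counts[["step2"]], 0L)
    expect_equal(ws$counts[["step3"]], 0L)
    expect_equal(nrow(ws$step3Clusters), 0L)
})

test_that("traitSimilarity correlates association patterns and clusters traits", {
    set.seed(57)
    n <- 200
    axis <- data.frame(dataset = rep(sprintf("d%d", 1:10), each = 20),
                       cell_type = rep(sprintf("ct%d", 1:20), 10))
    signal <- rexp(n, 0.2)
    mkTab <- function(drive, noise = 0.3, seed) {
        set.seed(seed)
        lp <- drive + rnorm(n, 0, noise)
        data.frame(axis, p = 10^(-pmax(lp, 0)),
                   significant = 10^(-pmax(lp, 0)) < 1e-3)
    }
    tabs <- list(A = mkTab(signal, seed = 1), B = mkTab(signal, seed = 2),
                 C = mkTab(rexp(n, 0.2), seed = 3))
    ts <- traitSimilarity(tabs)
    expect_equal(unname(diag(ts$rho)), rep(1, 3))
    expect_gt(ts$rho["A", "B"], 0.9)
    expect_lt(abs(ts$rho["A", "C"]), 0.2)
    expect_setequal(ts$order, c("A", "B", "C"))
    # annotation-based category proportions
    ann <- data.frame(axis, category = rep(c("neuron", "immune"), 100))
    ts2 <- traitSimilarity(tabs, annotation = ann)
    expect_equal(dim(ts2$proportions), c(3L, 2L))
    expect_true(all(ts2$proportions >= 0 & ts2$proportions <= 1))
    # mismatched axes error
    bad <- tabs
    bad$C <- bad$C[-1, ]
    expect_error(traitSimilarity(bad), "axis")
    expect_error(traitSimilarity(tabs[1]), "two traits")
})
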