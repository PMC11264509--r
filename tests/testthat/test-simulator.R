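test_that("a silenced promoter yields pure exponential mRNA decay", {
    kin <- data.frame(s0 = 0, d0 = 0.5, s1 = 1, d1 = 0.1,
                      konMin = 0, konMax = 0, koffMin = 1, koffMax = 1,
                      betaKon = 0, betaKoff = 0)
    grn <- GRN("A", stimuli = character(0), kinetics = kin)
    cells <- new("CellPopulation",
                 promoterState = matrix(0, 3, 1),
                 mrna = matrix(c(5, 20, 0), 3, 1),
                 protein = matrix(0, 3, 1))
    sim <- simulateGRN(grn, cells, duration = 6, recordTimes = c(2, 6),
                       step = 0.7, seed = 1)
    for (k in seq_along(sim)) {
        t <- timeStamp(sim[[k]])
        expect_equal(counts(sim[[k]])[, 1], c(5, 20, 0) * exp(-0.5 * t),
                     tolerance = 1e-9)
    }
})

test_that("an isolated constant-rate gene reaches the two-state stationary mean", {
    grn <- constantRateGene(s0 = 12, d0 = 0.4, kon = 0.8, koff = 1.2)
    m <- stationarySample(grn, nCells = 800, duration = 50, seed = 3)[, 1]
    mu <- telegraphMean(12, 0.4, 0.8, 1.2)
    expect_lt(abs(mean(m) - mu), 3 * mcSE(m))
    # and the stationary variance of the bursting model (Beta-distributed
    # occupancy): Var = scale^2 * ab / ((a+b)^2 (a+b+1)), a = kon/d0, b = koff/d0
    a <- 0.8 / 0.4
    b <- 1.2 / 0.4
    v <- (12 / 0.4)^2 * a * b / ((a + b)^2 * (a + b + 1))
    se2 <- var(m) * sqrt(2 / (length(m) - 1))  # rough SE of a variance
    expect_lt(abs(var(m) - v), 4 * se2)
})

test_that("simulation is bit-identical under a fixed seed and differs without one", {
    grn <- twoGeneGRN(2)
    init <- zeroData(40, c("A", "B"), value = 8)
    cells <- initializeCells(grn, init, 40, seed = 5)
    s1 <- simulateGRN(grn, cells, duration = 10, seed = 11)
    s2 <- simulateGRN(grn, cells, duration = 10, seed = 11)
    s3 <- simulateGRN(grn, cells, duration = 10, seed = 12)
    expect_identical(counts(s1[[1]]), counts(s2[[1]]))
    expect_false(identical(counts(s1[[1]]), counts(s3[[1]])))
})

test_that("mRNA and protein stay non-negative and finite along random simulations", {
    for (seed in 1:3) {
        grn <- randomGRN(nGenes = 4, seed = seed)
        cells <- initializeCells(grn, zeroData(30, geneNames(grn), value = 10),
                                 30, seed = seed)
        sim <- simulateGRN(grn, cells, duration = 30,
                           recordTimes = c(5, 15, 30), seed = seed)
        for (s in sim) expect_true(all(is.finite(counts(s)) & counts(s) >= 0))
        fin <- attr(sim, "finalState")
        expect_true(all(fin@mrna >= 0) && all(fin@protein >= 0))
        expect_true(all(fin@promoterState %in% c(0, 1)))
    }
})

test_that("halving the rate-refresh step leaves the stationary mean within Monte-Carlo error", {
    grn <- twoGeneGRN(2.5)  # regulated gene, so the refresh actually matters
    mCoarse <- stationarySample(grn, 600, duration = 50, seed = 21,
                                step = 0.2)[, "B"]
    mFine <- stationarySample(grn, 600, duration = 50, seed = 22,
                              step = 0.1)[, "B"]
    expect_lt(abs(mean(mCoarse) - mean(mFine)),
              3 * sqrt(mcSE(mCoarse)^2 + mcSE(mFine)^2))
})

test_that("knocked-out genes stay at zero mRNA at every record time", {
    grn <- applyKnockout(twoGeneGRN(3), "A")
    cells <- initializeCells(grn, zeroData(50, c("A", "B"), value = 9), 50,
                             seed = 2)
    sim <- simulateGRN(grn, cells, duration = 40, recordTimes = c(10, 40),
                       seed = 2)
    for (s in sim) expect_true(all(counts(s)[, "A"] == 0))
})

test_that("cells initialize from data rows, quasi-steady-state proteins and basal promoters", {
    grn <- GRN(c("A", "B"))
    zero <- zeroData(10, c("A", "B"))
    cells <- initializeCells(grn, zero, 25, seed = 1)
    expect_true(all(cells@mrna == 0) && all(cells@protein == 0))

    m <- matrix(c(1, 2, 3, 4, 10, 20, 30, 40), 4, 2,
                dimnames = list(NULL, c("A", "B")))
    cm <- CountMatrix(m)
    # without replacement and nCells = rows: a row permutation of the data
    cells <- initializeCells(grn, cm, 4, replace = FALSE, seed = 7)
    expect_setequal(cells@mrna[, "A"], m[, "A"])
    rowIdx <- match(cells@mrna[, "A"], m[, "A"])
    expect_identical(cells@mrna[, "B"], m[rowIdx, "B"])
    # quasi-steady state: P = (s1/d1) M
    k <- kinetics(grn)
    expect_equal(cells@protein,
                 sweep(cells@mrna, 2, k$s1 / k$d1, "*"))
    # determinism
    c1 <- initializeCells(grn, cm, 40, seed = 9)
    c2 <- initializeCells(grn, cm, 40, seed = 9)
    expect_identical(c1@mrna, c2@mrna)
    expect_identical(c1@promoterState, c2@promoterState)
    # marginal mode loses row coupling but keeps per-gene support
    c3 <- initializeCells(grn, cm, 200, mode = "marginals", seed = 3)
    expect_true(all(c3@mrna[, "A"] %in% m[, "A"]))
    expect_true(all(c3@mrna[, "B"] %in% m[, "B"]))
    # missing genes are an error
    expect_error(initializeCells(GRN(c("A", "C")), cm), "missing genes")
})

test_that("recording at time zero returns the starting state and integer emission rounds it", {
    grn <- constantRateGene()
    cm <- CountMatrix(matrix(c(3.3, 7.7), 2, 1, dimnames = list(NULL, "A")))
    cells <- initializeCells(grn, cm, 2, replace = FALSE, seed = 1)
    sim <- simulateGRN(grn, cells, duration = 5, recordTimes = c(0, 5),
                       seed = 1)
    expect_equal(sort(counts(sim[[1]])[, 1]), c(3.3, 7.7))
    expect_equal(timeStamp(sim[[1]]), 0)
    simInt <- simulateGRN(grn, cells, duration = 5, seed = 1,
                          emitIntegerCounts = TRUE)
    expect_true(all(counts(simInt[[1]]) == round(counts(simInt[[1]]))))
})
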