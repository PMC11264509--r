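test_that("sign categorization maps strengths to {-1, 0, 1}", {
    expect_identical(iota(2.5), 1L)
    expect_identical(iota(0), 0L)
    expect_identical(iota(-0.3), -1L)
    expect_identical(iota(c(-2, 0, 1e-9)), c(-1L, 0L, 1L))
    expect_error(iota(NaN), "finite")
    expect_error(iota(Inf), "finite")
})

test_that("pairwise difference counting matches a naive double-loop recount", {
    naive <- function(a, b) {
        d <- 0L
        for (i in seq_along(geneNames(a)))
            for (j in seq_along(geneNames(a)))
                if (iota(geneInteractions(a)[i, j]) !=
                    iota(geneInteractions(b)[i, j])) d <- d + 1L
        for (i in seq_along(geneNames(a)))
            for (s in seq_along(stimulusNames(a)))
                if (iota(stimulusInteractions(a)[i, s]) !=
                    iota(stimulusInteractions(b)[i, s])) d <- d + 1L
        d
    }
    set.seed(10)
    truth <- randomGRN(nGenes = 5, seed = 10)
    ens <- makeEnsemble(truth, nVariants = 6, flipRate = 0.3, seed = 11)
    for (i in 1:5) for (j in (i + 1):6) {
        expect_identical(pairwiseDifferences(ens[[i]], ens[[j]]),
                         naive(ens[[i]], ens[[j]]))
        expect_identical(pairwiseDifferences(ens[[i]], ens[[j]]),
                         pairwiseDifferences(ens[[j]], ens[[i]]))
    }
    expect_identical(pairwiseDifferences(truth, truth), 0L)
    G <- length(geneNames(truth))
    S <- length(stimulusNames(truth))
    expect_lte(pairwiseDifferences(ens[[1]], ens[[2]]), G * (G + S))
    expect_error(pairwiseDifferences(truth, randomGRN(nGenes = 4, seed = 1)),
                 "identical gene")
})

test_that("a single flipped edge counts as one difference and stimulus edges are switchable", {
    a <- GRN(c("A", "B"))
    gi <- geneInteractions(a)
    gi["B", "A"] <- 2
    geneInteractions(a) <- gi
    b <- a
    gi["B", "A"] <- -1.5
    geneInteractions(b) <- gi
    expect_identical(pairwiseDifferences(a, b), 1L)
    si <- stimulusInteractions(b)
    si["A", "S"] <- 1
    stimulusInteractions(b) <- si
    expect_identical(pairwiseDifferences(a, b), 2L)
    expect_identical(pairwiseDifferences(a, b, includeStimulus = FALSE), 1L)
})

test_that("mean pairwise differences averages over unordered pairs", {
    base <- GRN(c("A", "B"), stimuli = character(0))
    withEdges <- function(edges) {
        g <- base
        gi <- geneInteractions(g)
        for (e in edges) gi[e[1], e[2]] <- 1
        geneInteractions(g) <- gi
        g
    }
    a <- withEdges(list())
    b <- withEdges(list(c("B", "A")))
    c3 <- withEdges(list(c("A", "B"), c("A", "A")))
    # d(a,b) = 1, d(a,c) = 2, d(b,c) = 3: mean 2
    ens <- GRNEnsemble(list(a, b, c3))
    expect_equal(meanPairwiseDifferences(ens), 2)
    expect_equal(meanPairwiseDifferences(GRNEnsemble(list(a, a, a, a))), 0)
})

test_that("variance indices measure across-ensemble disagreement about a gene's edges", {
    base <- GRN(c("A", "B", "C"), stimuli = character(0))
    setEdge <- function(g, tgt, src, v) {
        gi <- geneInteractions(g)
        gi[tgt, src] <- v
        geneInteractions(g) <- gi
        g
    }
    # constant outgoing edges across the ensemble: DVI = 0
    g1 <- setEdge(base, "B", "A", 2)
    ens0 <- GRNEnsemble(list(g1, g1, g1))
    expect_equal(unname(dvi(ens0, "A")), 0)
    # one child edge with categories (+1, -1) in 2 GRNs: population Var = 1
    g2 <- setEdge(base, "B", "A", -3)
    ens1 <- GRNEnsemble(list(g1, g2))
    expect_equal(unname(dvi(ens1, "A")), 1)
    expect_equal(unname(dvi(ens1, "A", variance = "sample")), 2)
    # incoming edges count for AVI, not DVI
    expect_equal(unname(avi(ens1, "B")), 1)
    expect_equal(unname(dvi(ens1, "B")), 0)
    expect_equal(unname(avi(ens1, "A")), 0)
    expect_error(dvi(ens1, "nope"), "unknown gene")
})

test_that("AVI includes stimulus parents and both indices ignore uniform magnitude rescaling", {
    truth <- randomGRN(nGenes = 5, seed = 12)
    ens <- makeEnsemble(truth, nVariants = 8, flipRate = 0.25, seed = 13)
    scaled <- GRNEnsemble(lapply(seq_len(length(ens)), function(i) {
        g <- ens[[i]]
        g@geneInteraction <- 3.7 * g@geneInteraction
        g@stimulusInteraction <- 3.7 * g@stimulusInteraction
        g
    }))
    expect_equal(dvi(ens), dvi(scaled))
    expect_equal(avi(ens), avi(scaled))
    # stimulus contribution is real: compare with and without it
    withS <- avi(ens)
    withoutS <- avi(ens, includeStimulus = FALSE)
    expect_true(all(withS >= withoutS))
})

test_that("merging averages interactions and kinetics; singletons and identical members are fixed points", {
    truth <- randomGRN(nGenes = 4, seed = 14)
    ens <- makeEnsemble(truth, nVariants = 5, flipRate = 0.3, seed = 15)
    expect_equal(mergeGRNs(ens, 3), ens[[3]])
    same <- GRNEnsemble(list(truth, truth, truth))
    expect_equal(mergeGRNs(same), truth)

    a <- GRN(c("A", "B"), stimuli = character(0))
    gi <- geneInteractions(a)
    gi["B", "A"] <- 2
    b <- a
    geneInteractions(b) <- gi
    m <- mergeGRNs(GRNEnsemble(list(a, b)))
    expect_equal(geneInteractions(m)["B", "A"], 1)

    # union support: any edge present in some member survives (no exact
    # cancellation here since magnitudes are iid continuous)
    merged <- mergeGRNs(ens)
    support <- Reduce(`|`, lapply(seq_len(length(ens)), function(i)
        geneInteractions(ens[[i]]) != 0))
    expect_true(all((geneInteractions(merged) != 0) == support))
})
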