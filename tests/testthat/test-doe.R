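## Helpers to build tiny ensembles with prescribed edges from a target gene.

edgeEnsemble <- function(edgeList, genes = c("T", "X", "Y")) {
    base <- GRN(genes, stimuli = character(0))
    grns <- lapply(edgeList, function(edges) {
        g <- base
        gi <- geneInteractions(g)
        for (e in edges) gi[e$to, e$from] <- e$theta
        geneInteractions(g) <- gi
        g
    })
    GRNEnsemble(grns)
}

test_that("response-count entropy uses renormalized proportions in natural log", {
    expect_equal(perturbationEntropy(c(88, 45, 102, rep(0, 46))), 1.0466,
                 tolerance = 5e-5)
    expect_equal(perturbationEntropy(c(7, 364, 178)), 0.6933,
                 tolerance = 5e-5)
    # two equal groups: ln 2, whatever the count and zero padding
    for (k in c(1, 17, 364))
        expect_equal(perturbationEntropy(c(k, k, rep(0, 10))), log(2))
    expect_equal(perturbationEntropy(rep(0, 49)), 0)
    expect_equal(perturbationEntropy(c(0, 5, 0)), 0)  # single responder
    expect_error(perturbationEntropy(c(1, -2)), ">= 0")
})

test_that("chance-accuracy probability is the binomial lower tail, checked by enumeration", {
    # brute force over all 2^5 error patterns at n = 5, p = 0.5
    pats <- expand.grid(rep(list(0:1), 5))
    oracle <- sum(rowSums(pats) <= 2) / 2^5
    expect_equal(predictionAccuracyProbability(5, 2, 0.5), oracle)
    # general p by direct summation
    direct <- sum(vapply(0:3, function(k)
        choose(8, k) * 0.3^k * 0.7^(8 - k), numeric(1)))
    expect_equal(predictionAccuracyProbability(8, 3, 0.3), direct)
    expect_equal(predictionAccuracyProbability(7, 7, 0.9), 1)
    expect_error(predictionAccuracyProbability(5, 6, 0.5), "maxErrors")
})

test_that("screening a strong activator's knock-out calls its target down", {
    # bursty kinetics with expression to lose, one strong edge T -> X
    grn <- GRN(c("T", "X"), stimuli = character(0),
               kinetics = twoGeneGRN(3)@kinetics,
               proteinThreshold = 30)
    gi <- geneInteractions(grn)
    gi["X", "T"] <- 3
    geneInteractions(grn) <- gi
    ens <- GRNEnsemble(list(grn))
    init <- zeroData(100, c("T", "X"), value = 10)
    tab <- screenPerturbation(ens, Perturbation("T", "KO"), init,
                              nCells = 150, duration = 60, seed = 4)
    eff <- tab@effects
    down <- eff[eff$gene == "X" & eff$direction == "down", ]
    expect_true(down$significant)
    # the target itself is excluded from the calls
    expect_false("T" %in% eff$gene)
    # fixed seed: identical table on rerun
    tab2 <- screenPerturbation(ens, Perturbation("T", "KO"), init,
                               nCells = 150, duration = 60, seed = 4)
    expect_identical(tab@effects, tab2@effects)
})

test_that("perturbing an unconnected gene produces no significant downstream calls", {
    ens <- edgeEnsemble(rep(list(list()), 3))
    init <- zeroData(80, c("T", "X", "Y"), value = 10)
    tab <- screenPerturbation(ens, Perturbation("T", "KO"), init,
                              nCells = 100, duration = 40, seed = 6)
    expect_equal(sum(tab@effects$significant), 0)
})

test_that("effect summaries recount the table and flag all-or-none responders", {
    pert <- Perturbation("T", "KO")
    ens <- edgeEnsemble(list(
        list(list(from = "T", to = "X", theta = 2)),
        list(list(from = "T", to = "X", theta = 1),
             list(from = "T", to = "Y", theta = -1)),
        list()))
    mkRow <- function(grn, gene, dir, sig)
        data.frame(grn = grn, gene = gene, direction = dir, rawP = 0.001,
                   adjustedP = 0.004, significant = sig)
    eff <- rbind(mkRow("grn001", "X", "down", TRUE),
                 mkRow("grn002", "X", "down", TRUE),
                 mkRow("grn003", "X", "down", TRUE),
                 mkRow("grn002", "Y", "up", TRUE),
                 mkRow("grn003", "Y", "down", FALSE))
    tab <- new("EffectTable", effects = eff, perturbation = pert,
               alpha = 0.01, data = list())
    sm <- summarizeEffects(tab, ens)
    tb <- sm@table
    expect_equal(tb$nVarying[tb$gene == "X"], 3)
    expect_equal(tb$nVarying[tb$gene == "Y"], 1)
    expect_equal(tb$nInteracting[tb$gene == "X"], 2)
    expect_equal(tb$nInteracting[tb$gene == "Y"], 1)
    # X responds in all 3 members: all-or-none, hence uninformative
    expect_true(tb$uninformative[tb$gene == "X"])
    expect_false(tb$uninformative[tb$gene == "Y"])
    expect_equal(tb$direction[tb$gene == "Y"], "up")
    # entropy from the summary counts (3, 1)
    expect_equal(perturbationEntropy(sm), perturbationEntropy(c(3, 1)))
})

test_that("responses do not exceed carriers on a direct-edges-only screen", {
    # star ensemble: the only edges run from T to its children, so every
    # response must be direct (no cascades) and FP-free at alpha 0.01
    grns <- lapply(1:6, function(v) {
        g <- twoGeneGRN(3)
        g <- GRN(c("T", "X", "Y"), stimuli = character(0),
                 kinetics = g@kinetics[c(1, 1, 1), ],
                 proteinThreshold = 30)
        gi <- geneInteractions(g)
        if (v <= 4) gi["X", "T"] <- 3
        if (v <= 2) gi["Y", "T"] <- -3
        geneInteractions(g) <- gi
        g
    })
    ens <- GRNEnsemble(grns)
    init <- zeroData(100, c("T", "X", "Y"), value = 10)
    tab <- screenPerturbation(ens, Perturbation("T", "KO"), init,
                              nCells = 150, duration = 60, seed = 9)
    sm <- summarizeEffects(tab, ens)
    expect_true(all(sm@table$nVarying <= sm@table$nInteracting))
    expect_equal(sm@table$nInteracting[sm@table$gene == "X"], 4)
    expect_equal(sm@table$nInteracting[sm@table$gene == "Y"], 2)
})

test_that("perturbation ranking is by descending entropy with deterministic ties", {
    mkSummary <- function(target, counts) {
        n <- length(counts)
        tb <- data.frame(gene = sprintf("d%02d", seq_len(n)),
                         nDown = counts, nUp = 0, nVarying = counts,
                         nInteracting = counts,
                         direction = ifelse(counts > 0, "down", "none"),
                         uninformative = counts %in% c(0, 364))
        new("EffectSummary", table = tb, ensembleSize = 364,
            perturbation = Perturbation(target, "KO"))
    }
    sums <- list(
        mkSummary("DHCR7", c(6, 1, rep(0, 47))),
        mkSummary("FNIP1", c(88, 45, 102, rep(0, 46))),
        mkSummary("FHL3", c(364, 8, 0, rep(0, 46))),
        mkSummary("BATF", c(7, 364, 178, rep(0, 46))),
        mkSummary("MID2", c(7, 0, 39, rep(0, 46))))
    rk <- rankPerturbations(sums)
    expect_identical(rk$target, c("FNIP1", "BATF", "MID2", "DHCR7", "FHL3"))
    # input order is irrelevant
    expect_identical(rankPerturbations(rev(sums))$target, rk$target)
    # ties break alphabetically
    tied <- rankPerturbations(list(mkSummary("ZZZ", c(2, 2)),
                                   mkSummary("AAA", c(5, 5))))
    expect_identical(tied$target, c("AAA", "ZZZ"))
    expect_identical(rankPerturbations(sums[2])$target, "FNIP1")
})

test_that("pooled predictions equal direct tests on the concatenated samples", {
    grns <- lapply(1:5, function(v) {
        g <- GRN(c("T", "X"), stimuli = character(0),
                 kinetics = twoGeneGRN(3)@kinetics[c(1, 1), ],
                 proteinThreshold = 30)
        gi <- geneInteractions(g)
        if (v <= 2) gi["X", "T"] <- 3  # 40% of members carry the edge
        geneInteractions(g) <- gi
        g
    })
    ens <- GRNEnsemble(grns)
    init <- zeroData(100, c("T", "X"), value = 10)
    tab <- screenPerturbation(ens, Perturbation("T", "KO"), init,
                              nCells = 120, duration = 60, seed = 13,
                              keepData = TRUE)
    pooled <- pooledPrediction(tab)
    expect_identical(unique(pooled@effects$grn), "pooled")
    # oracle: one-sided Welch test on the row-bound matrices
    refAll <- do.call(rbind, lapply(tab@data, `[[`, "ref"))
    pertAll <- do.call(rbind, lapply(tab@data, `[[`, "pert"))
    pOracle <- t.test(pertAll[, "X"], refAll[, "X"],
                      alternative = "less")$p.value
    expect_equal(pooled@effects$rawP[pooled@effects$gene == "X" &
                                     pooled@effects$direction == "down"],
                 pOracle)
    # with 40% strong carriers the pooled down call fires
    expect_true(pooled@effects$significant[pooled@effects$gene == "X" &
                                           pooled@effects$direction == "down"])
    expect_error(pooledPrediction(screenPerturbation(
        ens, Perturbation("T", "KO"), init, nCells = 20, duration = 5,
        seed = 1)), "keepData")
})

test_that("selection keeps exactly the GRNs whose edge signs explain an observation", {
    ens <- edgeEnsemble(list(
        list(list(from = "T", to = "X", theta = 2)),
        list(list(from = "T", to = "X", theta = 0.4)),
        list(list(from = "T", to = "X", theta = -1)),
        list()))
    expect_identical(selectGRNs(ens, "T", c(X = "down")), c(1L, 2L))
    expect_identical(selectGRNs(ens, "T", c(X = "up")), 3L)
    # no member has an edge to Y: empty selection
    expect_identical(selectGRNs(ens, "T", c(Y = "down")), integer(0))
    # "none" entries are ignored, absence of usable observations errors
    expect_identical(selectGRNs(ens, "T", c(X = "down", Y = "none")),
                     c(1L, 2L))
    expect_error(selectGRNs(ens, "T", c(X = "none")), "no observed effects")
    expect_error(selectGRNs(ens, "Z", c(X = "down")), "unknown gene")
    # veto mode drops sign-contradicting members
    ens2 <- edgeEnsemble(list(
        list(list(from = "T", to = "X", theta = 2)),
        list(list(from = "T", to = "X", theta = 2),
             list(from = "T", to = "Y", theta = 2))))
    expect_identical(selectGRNs(ens2, "T", c(X = "down", Y = "up")),
                     c(1L, 2L))
    expect_identical(selectGRNs(ens2, "T", c(X = "down", Y = "up"),
                                veto = TRUE), 1L)
})

test_that("adding observations can only grow the selected set", {
    set.seed(33)
    truth <- randomGRN(nGenes = 5, seed = 34)
    ens <- makeEnsemble(truth, nVariants = 12, flipRate = 0.3, seed = 35)
    genes <- geneNames(truth)
    for (rep in 1:5) {
        target <- sample(genes, 1)
        others <- setdiff(genes, target)
        obs1 <- setNames(sample(c("down", "up"), 2, TRUE), sample(others, 2))
        extra <- setdiff(others, names(obs1))[1]
        obs2 <- c(obs1, setNames(sample(c("down", "up"), 1), extra))
        s1 <- tryCatch(selectGRNs(ens, target, obs1),
                       error = function(e) integer(0))
        s2 <- tryCatch(selectGRNs(ens, target, obs2),
                       error = function(e) integer(0))
        expect_true(all(s1 %in% s2))
    }
})
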