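## Shared fixture builders. Everything is generated in code; no data files.

## Single gene with constant promoter switching rates (beta = 0 pins the
## rates at their minima), no regulators.
constantRateGene <- function(s0 = 10, d0 = 0.5, kon = 1, koff = 1,
                             s1 = 1, d1 = 0.1) {
    kin <- data.frame(s0 = s0, d0 = d0, s1 = s1, d1 = d1,
                      konMin = kon, konMax = kon + 1,
                      koffMin = koff, koffMax = koff + 1,
                      betaKon = 0, betaKoff = 0)
    GRN("A", stimuli = character(0), kinetics = kin)
}

## Two genes, A activates (or represses) B with strength theta.
twoGeneGRN <- function(theta = 3) {
    grn <- GRN(c("A", "B"), stimuli = character(0),
               kinetics = data.frame(s0 = 10, d0 = 0.5, s1 = 1, d1 = 0.1,
                                     konMin = 0.05, konMax = 2,
                                     koffMin = 0.5, koffMax = 0.5,
                                     betaKon = 0.25, betaKoff = 0.25),
               proteinThreshold = 30)
    gi <- geneInteractions(grn)
    gi["B", "A"] <- theta
    geneInteractions(grn) <- gi
    grn
}

## All-zero (or constant) starting data for n cells.
zeroData <- function(n, genes = "A", value = 0) {
    CountMatrix(matrix(value, n, length(genes),
                       dimnames = list(NULL, genes)))
}

## Cell population started empty with all promoters off.
emptyCells <- function(n, genes) {
    z <- matrix(0, n, length(genes), dimnames = list(NULL, genes))
    new("CellPopulation", promoterState = z, mrna = z, protein = z)
}

## Stationary mRNA mean of an isolated constant-rate gene.
telegraphMean <- function(s0, d0, kon, koff) s0 * kon / (d0 * (kon + koff))

## Monte-Carlo standard error of a sample mean.
mcSE <- function(x) sd(x) / sqrt(length(x))

## Draw a stationary sample of an isolated constant-rate gene.
stationarySample <- function(grn, nCells, duration = 60, seed = 1,
                             step = 0.1) {
    cells <- initializeCells(grn, zeroData(nCells, geneNames(grn)),
                             nCells, seed = seed)
    counts(simulateGRN(grn, cells, duration = duration, step = step,
                       seed = seed + 1)[[1L]])
}

## Small random GRN with edges, stimuli and heterogeneous kinetics, for
## round-trip and property tests.
randomGRN <- function(nGenes = 4, seed = 1) {
    makeTruthGRN(nGenes = nGenes, edgeDensity = 0.4, seed = seed)
}

## Single-gene balancing fixture with a known optimum: initial data drawn
## from a long stationary run at betaStar, so balancing should recover a
## cost near the sampling-noise floor.
balancingFixture <- function(betaStar = c(2, 0.5), nCells = 300, seed = 55) {
    kin <- data.frame(s0 = 10, d0 = 0.5, s1 = 1, d1 = 0.1,
                      konMin = 0.1, konMax = 2, koffMin = 0.4,
                      koffMax = 1.6,
                      betaKon = betaStar[1], betaKoff = betaStar[2])
    grn <- GRN("A", stimuli = character(0), kinetics = kin)
    cells <- initializeCells(grn, zeroData(nCells), nCells, seed = seed)
    sim <- simulateGRN(grn, cells, duration = 150, step = 0.1,
                       seed = seed + 1)
    init <- CountMatrix(counts(sim[[1L]]), time = 0, condition = "t0")
    # hand the caller a GRN that does NOT start at the optimum
    grn@kinetics$betaKon <- 1
    grn@kinetics$betaKoff <- 1
    list(grn = grn, init = init, betaStar = betaStar)
}
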