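## Synthetic ground truths, ensembles of near-identical candidate GRNs and
## simulated "experimental" datasets, for end-to-end exercise of the whole
## design-of-experiment loop without any external data.

.edgeMagnitude <- function(n) runif(n, 2, 4)

#' Generate a random ground-truth GRN
#'
#' Draws a signed random topology at the requested edge density (no
#' self-loops; the stimulus activates at least one root gene), with bursty
#' two-state kinetics drawn from narrow ranges and interaction thresholds
#' placed at half of each regulator's basal protein scale so that regulation
#' is active in the simulated regime.  Edge strengths are drawn uniformly in
#' [2, 4] in magnitude (60% activating), i.e. 7- to 55-fold modulation of
#' the promoter interaction term.  Burst regulation acts on frequency:
#' `koff` is constant per gene.
#'
#' @param nGenes number of genes (default 8).
#' @param nStimuli number of stimuli (default 1).
#' @param edgeDensity probability of a directed gene-gene edge (default
#'   0.25).
#' @param nRoots number of genes directly activated by each stimulus
#'   (default 1).
#' @param seed optional integer seed.
#' @return a [GRN-class].
#' @export
makeTruthGRN <- function(nGenes = 8, nStimuli = 1, edgeDensity = 0.25,
                         nRoots = 1, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    genes <- sprintf("g%02d", seq_len(nGenes))
    stimuli <- if (nStimuli > 0) sprintf("S%d", seq_len(nStimuli))
               else character(0)
    kin <- data.frame(
        s0 = runif(nGenes, 8, 15),
        d0 = runif(nGenes, 0.3, 0.6),
        s1 = runif(nGenes, 0.5, 2),
        d1 = runif(nGenes, 0.05, 0.15),
        konMin = runif(nGenes, 0.05, 0.15),
        konMax = runif(nGenes, 1.5, 2.5),
        koffMin = 0, koffMax = 0,
        betaKon = 0.25, betaKoff = 0.25)
    koff <- runif(nGenes, 0.4, 0.7)
    kin$koffMin <- koff
    kin$koffMax <- koff
    thetaP <- matrix(0, nGenes, nGenes)
    off <- which(row(thetaP) != col(thetaP))
    edges <- off[runif(length(off)) < edgeDensity]
    signs <- ifelse(runif(length(edges)) < 0.6, 1, -1)
    thetaP[edges] <- signs * .edgeMagnitude(length(edges))
    thetaQ <- matrix(0, nGenes, max(nStimuli, 0))
    if (nStimuli > 0)
        for (s in seq_len(nStimuli))
            thetaQ[sample.int(nGenes, min(nRoots, nGenes)), s] <- 3
    # basal protein scale at beta*Phi = 0.25: thresholds at half of it
    konB <- (kin$konMin + kin$konMax * 0.25) / 1.25
    pOn <- konB / (konB + koff)
    pScale <- (kin$s1 / kin$d1) * (kin$s0 / kin$d0) * pOn
    GRN(genes, stimuli,
        geneInteraction = thetaP, stimulusInteraction = thetaQ,
        kinetics = kin,
        proteinThreshold = pmax(pScale / 2, 1),
        stimulusThreshold = 0.5)
}

#' Expected per-entry flip rate for a target difference count
#'
#' Under the variant model of [makeEnsemble()], two independent variants
#' disagree at a given interaction entry with probability
#' \eqn{q = 2r(1-r) + r^2/2} (one of the two flipped, or both flipped to
#' different categories).  Given a desired mean number of pairwise
#' differences over `nEntries` interaction entries, this inverts the
#' quadratic to the per-entry flip rate r.
#'
#' @param targetMeanDiff desired mean pairwise difference count.
#' @param nEntries number of interaction entries in the topology (gene-gene
#'   plus stimulus-gene).
#' @return the flip rate r in \[0, 1\].
#' @examples
#' calibrateFlipRate(7.72, 160)  # per-entry diversity of a 49-gene ensemble
#' @export
calibrateFlipRate <- function(targetMeanDiff, nEntries) {
    q <- targetMeanDiff / nEntries
    stopifnot(q >= 0, q <= 5 / 6)
    # q = 2r - 3r^2/2  =>  r = (2 - sqrt(4 - 6q)) / 3
    (2 - sqrt(4 - 6 * q)) / 3
}

#' Generate an ensemble of near-identical candidate GRNs
#'
#' Each variant copies the truth, then independently re-categorizes every
#' interaction entry (gene-gene and stimulus-gene) with probability
#' `flipRate`: the entry's sign category jumps uniformly to one of the
#' other two categories, with a freshly drawn magnitude for non-zero
#' outcomes.  Kinetics and thresholds are shared with the truth, isolating
#' topology effects.  The truth itself is not a member.
#'
#' @param truth the ground-truth [GRN-class].
#' @param nVariants number of candidate GRNs (default 30).
#' @param flipRate per-entry re-categorization probability; the default
#'   reproduces the per-pair difference count of a typical inferred
#'   ensemble (about 7.7 differing entries between two members,
#'   concentrated over the desk-scale topology; see [calibrateFlipRate()]).
#' @param seed optional integer seed.
#' @return a [GRNEnsemble-class].
#' @export
makeEnsemble <- function(truth, nVariants = 30, flipRate = NULL,
                         seed = NULL) {
    stopifnot(is(truth, "GRN"), nVariants >= 2)
    if (!is.null(seed)) set.seed(seed)
    G <- length(truth@genes)
    S <- length(truth@stimuli)
    if (is.null(flipRate))
        flipRate <- calibrateFlipRate(7.7, G * G + G * S)
    flipEntries <- function(m) {
        flip <- which(runif(length(m)) < flipRate)
        for (k in flip) {
            cur <- iota(m[k])
            newCat <- sample(setdiff(c(-1L, 0L, 1L), cur), 1L)
            m[k] <- if (newCat == 0L) 0 else newCat * .edgeMagnitude(1L)
        }
        m
    }
    grns <- lapply(seq_len(nVariants), function(v) {
        g <- truth
        g@geneInteraction <- flipEntries(g@geneInteraction)
        if (S) g@stimulusInteraction <- flipEntries(g@stimulusInteraction)
        g
    })
    GRNEnsemble(grns)
}

## Stimulus-off copy of a GRN (all profiles clamped to level 0).
.stimulusOff <- function(grn) {
    grn@stimulusProfile <- rep(list(cbind(time = 0, level = 0)),
                               length(grn@stimuli))
    grn
}

#' Pre-stimulation stationary snapshot of a GRN
#'
#' Emulates the t = 0 single-cell dataset of an experiment: cells are run to
#' stationarity under the self-renewal condition (stimulus off) and their
#' mRNA quantities recorded.  Use the result as `initialData` for
#' [initializeCells()], [screenPerturbation()] and [balanceAll()].
#'
#' @param grn a [GRN-class].
#' @param nCells number of cells (default 200).
#' @param burnIn pre-run length in hours (default 50, several mRNA and
#'   protein lifetimes).
#' @param step rate-refresh interval, hours.
#' @param seed optional integer seed.
#' @return a [CountMatrix-class] at time 0, condition `"t0"`, with the full
#'   final [CellPopulation-class] attached as attribute `"state"`.
#' @export
syntheticInitialData <- function(grn, nCells = 200, burnIn = 50, step = 0.1,
                                 seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    off <- .stimulusOff(grn)
    G <- length(grn@genes)
    # start empty with promoters at their basal occupancy
    E <- matrix(0, nCells, G, dimnames = list(NULL, grn@genes))
    zero <- matrix(0, nCells, G, dimnames = list(NULL, grn@genes))
    Q0 <- rep(0, length(grn@stimuli))
    for (i in seq_len(G)) {
        kon <- konRate(off, i, rep(0, G), Q0)
        koff <- koffRate(off, i, rep(0, G), Q0)
        pOn <- if (kon + koff > 0) kon / (kon + koff) else 0
        E[, i] <- as.numeric(runif(nCells) < pOn)
    }
    cells <- new("CellPopulation", promoterState = E, mrna = zero,
                 protein = zero)
    sim <- simulateGRN(off, cells, duration = burnIn, recordTimes = burnIn,
                       step = step)
    out <- CountMatrix(counts(sim[[1L]]), time = 0, condition = "t0")
    attr(out, "state") <- attr(sim, "finalState")
    out
}

#' Simulate an "experimental" dataset from a (possibly perturbed) GRN
#'
#' Emulates the acquisition of time-stamped single-cell data: cells start
#' from the pre-stimulation stationary state of the network, the stimulus
#' switches on at t = 0 (with an optional perturbation applied), and mRNA
#' snapshots are recorded at the requested times.  Small `nCells` values
#' reproduce the low-cell-number regime of real perturbation experiments.
#'
#' @param grn the [GRN-class] to observe (typically a synthetic truth).
#' @param times record times in hours (time 0 returns the starting
#'   snapshot).
#' @param nCells number of cells per snapshot (default 200).
#' @param perturbation optional [Perturbation-class] applied at t = 0.
#' @param burnIn pre-stimulation run length, hours.
#' @param step rate-refresh interval, hours.
#' @param seed optional integer seed.
#' @return a list of [CountMatrix-class], one per requested time.
#' @export
makeObservations <- function(grn, times = c(0, 8, 24, 48, 72, 100),
                             nCells = 200, perturbation = NULL, burnIn = 50,
                             step = 0.1, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    t0 <- syntheticInitialData(grn, nCells = nCells, burnIn = burnIn,
                               step = step)
    cells <- attr(t0, "state")
    if (length(times) == 1L && times == 0) {
        out <- list(CountMatrix(counts(t0), time = 0,
                                condition = if (is.null(perturbation)) "WT"
                                            else paste0(perturbation@kind, ":",
                                                        perturbation@target)))
        return(out)
    }
    simulateGRN(grn, cells, duration = max(times),
                recordTimes = times, step = step,
                perturbation = perturbation)
}
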