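#' Initialize a population of cells from observed counts
#'
#' Draws each cell's mRNA vector from an observed (or previously simulated)
#' count matrix, sets proteins to their quasi-steady state
#' \eqn{(s_1/d_1)\,M}, and samples each promoter state from a Bernoulli with
#' probability \eqn{k_{on}/(k_{on}+k_{off})} evaluated at the cell's initial
#' protein levels and the stimulus levels at t = 0.  Knocked-out genes start
#' with zero mRNA and protein and their promoter off.
#'
#' @param grn a [GRN-class].
#' @param initialData a [CountMatrix-class] whose gene set covers the GRN's
#'   genes (typically the t = 0 snapshot of the training data).
#' @param nCells number of cells to create (default: the number of rows of
#'   `initialData`).
#' @param replace sample rows with replacement (default).  With
#'   `replace = FALSE` and `nCells` equal to the number of rows, the mRNA
#'   matrix is a row permutation of `initialData`.
#' @param mode `"rows"` (default) samples whole cells, preserving gene-gene
#'   correlations; `"marginals"` samples each gene's value independently from
#'   its marginal distribution.
#' @param seed optional integer seed for reproducibility.
#' @return a [CellPopulation-class].
#' @export
initializeCells <- function(grn, initialData, nCells = NULL, replace = TRUE,
                            mode = c("rows", "marginals"), seed = NULL) {
    mode <- match.arg(mode)
    stopifnot(is(grn, "GRN"), is(initialData, "CountMatrix"))
    if (!is.null(seed)) set.seed(seed)
    cm <- counts(initialData)
    if (nrow(cm) == 0L) stop("initialData has no cells")
    missing <- setdiff(grn@genes, colnames(cm))
    if (length(missing))
        stop("initialData is missing genes: ", paste(missing, collapse = ", "))
    cm <- cm[, grn@genes, drop = FALSE]
    if (is.null(nCells)) nCells <- nrow(cm)
    G <- length(grn@genes)
    if (mode == "rows") {
        rows <- sample.int(nrow(cm), nCells, replace = replace)
        M <- cm[rows, , drop = FALSE]
    } else {
        M <- vapply(seq_len(G), function(j)
            cm[sample.int(nrow(cm), nCells, replace = replace), j],
            numeric(nCells))
        dim(M) <- c(nCells, G)
    }
    dimnames(M) <- list(NULL, grn@genes)
    k <- grn@kinetics
    psRatio <- ifelse(k$d1 > 0, k$s1 / k$d1, 0)
    P <- sweep(M, 2L, psRatio, "*")
    Q0 <- stimulusLevels(grn, 0)
    E <- matrix(0, nCells, G, dimnames = list(NULL, grn@genes))
    for (cell in seq_len(nCells)) {
        for (i in seq_len(G)) {
            if (grn@knockedOut[i]) next
            kon <- konRate(grn, i, P[cell, ], Q0)
            koff <- koffRate(grn, i, P[cell, ], Q0)
            pOn <- if (kon + koff > 0) kon / (kon + koff) else 0
            E[cell, i] <- as.numeric(runif(1) < pOn)
        }
    }
    M[, grn@knockedOut] <- 0
    P[, grn@knockedOut] <- 0
    new("CellPopulation", promoterState = E, mrna = M, protein = P)
}

## Build the interval grid and per-interval stimulus levels for the C++ core.
.simulationGrid <- function(grn, duration, recordTimes, step) {
    stimBreaks <- unlist(lapply(grn@stimulusProfile, function(pf) pf[, 1L]))
    brks <- sort(unique(round(c(seq(0, duration, by = step), duration,
                                recordTimes,
                                stimBreaks[stimBreaks > 0 &
                                           stimBreaks < duration]), 9)))
    brks <- brks[brks >= 0 & brks <= duration]
    K <- length(brks) - 1L
    S <- length(grn@stimuli)
    Qmat <- matrix(0, K, max(S, 1L))
    if (S)
        for (k in seq_len(K))
            Qmat[k, ] <- stimulusLevels(grn, brks[k])
    recordAfter <- logical(K)
    for (rt in recordTimes[recordTimes > 0]) {
        k <- which(abs(brks[-1L] - rt) < 1e-8)
        if (!length(k)) stop("record time ", rt, " not on the time grid")
        recordAfter[k] <- TRUE
    }
    list(brks = brks, Qmat = Qmat, recordAfter = recordAfter)
}

#' Simulate a GRN as a population of independent cells
#'
#' Evolves each cell independently under the PDMP model: within each
#' rate-refresh interval of length `step`, the promoter switching rates are
#' held at their start-of-interval values (computed from the cell's current
#' protein levels and the stimulus profile), switch times are drawn from the
#' exact exponential waiting-time law, and mRNA/protein follow the
#' closed-form solutions of their linear kinetics between switches.  The
#' scheme is exact in the constant-rate limit and converges to the exact
#' PDMP law as `step` decreases.
#'
#' Knocked-out genes (see [applyKnockout()]) have their promoter forced off
#' throughout.  If `perturbation` is given, it is applied to `grn` first; for
#' a knock-out the target's mRNA and protein are also zeroed in the starting
#' population.
#'
#' @param grn a [GRN-class].
#' @param cells a [CellPopulation-class] starting state (see
#'   [initializeCells()]).
#' @param duration total simulated time, hours.
#' @param recordTimes times at which to record mRNA snapshots (default: the
#'   end of the simulation).  A record at time 0 returns the initial state.
#' @param step promoter-rate refresh interval, hours (default 0.1).
#' @param perturbation optional [Perturbation-class] applied before
#'   simulating.
#' @param frozenGenes genes whose state is held constant for the whole run
#'   (their proteins still regulate the others); used by the balancing
#'   procedure.
#' @param emitIntegerCounts if `TRUE`, recorded mRNA quantities are replaced
#'   by Poisson draws with the continuous quantity as intensity, mimicking
#'   molecule counting.
#' @param seed optional integer seed; identical inputs and seed give
#'   bit-identical output.
#' @param condition condition label stored in the returned matrices
#'   (default `"WT"`, or `"<kind>:<target>"` under a perturbation).
#' @return a list of [CountMatrix-class], one per record time, with the final
#'   [CellPopulation-class] attached as attribute `"finalState"`.
#' @examples
#' grn <- GRN("A")
#' init <- CountMatrix(matrix(rpois(50, 10), 50, 1,
#'                            dimnames = list(NULL, "A")))
#' cells <- initializeCells(grn, init, seed = 1)
#' sim <- simulateGRN(grn, cells, duration = 10, seed = 1)
#' sim[[1]]
#' @export
simulateGRN <- function(grn, cells, duration = 100, recordTimes = duration,
                        step = 0.1, perturbation = NULL,
                        frozenGenes = character(0),
                        emitIntegerCounts = FALSE, seed = NULL,
                        condition = NULL) {
    stopifnot(is(grn, "GRN"), is(cells, "CellPopulation"))
    if (duration <= 0) stop("duration must be > 0")
    if (step <= 0) stop("step must be > 0")
    if (any(recordTimes < 0 | recordTimes > duration))
        stop("recordTimes must lie in [0, duration]")
    if (nrow(cells@mrna) == 0L) stop("empty cell population")
    if (!is.null(perturbation)) {
        grn <- applyPerturbation(grn, perturbation)
        if (perturbation@kind == "KO") {
            i <- .geneIndex(grn, perturbation@target)
            cells@promoterState[, i] <- 0
            cells@mrna[, i] <- 0
            cells@protein[, i] <- 0
        }
        if (is.null(condition))
            condition <- paste0(perturbation@kind, ":", perturbation@target)
    }
    if (is.null(condition)) condition <- "WT"
    if (!is.null(seed)) set.seed(seed)
    frozen <- grn@genes %in% frozenGenes
    grid <- .simulationGrid(grn, duration, recordTimes, step)
    res <- .simulateCells(
        cells@promoterState, cells@mrna, cells@protein,
        grn@geneInteraction,
        grn@stimulusInteraction,
        unname(grn@proteinThreshold),
        if (length(grn@stimuli)) unname(grn@stimulusThreshold) else numeric(0),
        grn@hillExponent,
        as.matrix(grn@kinetics[, .kineticsCols]),
        unname(grn@knockedOut), frozen,
        grid$brks, grid$Qmat, grid$recordAfter)
    recTimes <- grid$brks[-1L][grid$recordAfter]
    out <- vector("list", length(recordTimes))
    sorted <- sort(recordTimes)
    for (r in seq_along(sorted)) {
        rt <- sorted[r]
        M <- if (rt == 0) cells@mrna
             else res$records[[which(abs(recTimes - rt) < 1e-8)]]
        colnames(M) <- grn@genes
        if (emitIntegerCounts)
            M <- matrix(stats::rpois(length(M), lambda = M), nrow(M), ncol(M),
                        dimnames = dimnames(M))
        out[[r]] <- CountMatrix(M, time = rt, condition = condition)
    }
    final <- new("CellPopulation",
                 promoterState = `dimnames<-`(res$E, dimnames(cells@mrna)),
                 mrna = `dimnames<-`(res$M, dimnames(cells@mrna)),
                 protein = `dimnames<-`(res$P, dimnames(cells@mrna)))
    attr(out, "finalState") <- final
    out
}
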