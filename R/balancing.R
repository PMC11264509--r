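## Basal-expression balancing: calibrate per-gene (betaKon, betaKoff) so
## that an unperturbed simulation holds the initial expression distribution
## stationary.  Each gene is balanced independently by freezing every other
## gene's state at its initialization value, which turns a G x 2 dimensional
## problem into G independent 2-dimensional ones.

.withBetas <- function(grn, gene, betaKon, betaKoff) {
    i <- .geneIndex(grn, gene)
    grn@kinetics$betaKon[i] <- betaKon
    grn@kinetics$betaKoff[i] <- betaKoff
    grn
}

#' Balancing cost for one gene
#'
#' Simulates only the focal gene for `config@horizon` hours (every other
#' gene's mRNA and protein frozen per cell at their initialization values),
#' then returns the 1-D Kantorovich distance between the focal gene's
#' simulated marginal at the horizon and its initial marginal, averaged over
#' `config@repeats` independent simulations.  A perfectly balanced gene has
#' a cost at the sampling-noise floor of [wasserstein1()] between two draws
#' of the same distribution.
#'
#' @param grn a [GRN-class].
#' @param gene focal gene name.
#' @param initialData [CountMatrix-class] covering all genes (the t = 0
#'   snapshot to hold stationary).
#' @param betaKon,betaKoff candidate basal adjustment values (>= 0).
#' @param config a [BalancingConfig-class].
#' @param seed optional integer seed.
#' @return a non-negative number.
#' @export
balanceCost <- function(grn, gene, initialData, betaKon, betaKoff,
                        config = BalancingConfig(), seed = NULL) {
    stopifnot(is(config, "BalancingConfig"))
    i <- .geneIndex(grn, gene)
    if (all(counts(initialData)[, gene] == 0) && grn@kinetics$s0[i] > 0)
        warning("initial data for ", gene,
                " are all zero but s0 > 0; balancing towards extinction")
    if (!is.null(seed)) set.seed(seed)
    g2 <- .withBetas(grn, gene, betaKon, betaKoff)
    others <- setdiff(g2@genes, gene)
    target0 <- counts(initialData)[, gene]
    costs <- vapply(seq_len(config@repeats), function(r) {
        cells <- initializeCells(g2, initialData, nCells = config@nCells)
        sim <- simulateGRN(g2, cells, duration = config@horizon,
                           recordTimes = config@horizon, step = config@step,
                           frozenGenes = others)
        wasserstein1(counts(sim[[1L]])[, gene], target0)
    }, numeric(1))
    mean(costs)
}

#' Balance one gene by noisy simulated annealing
#'
#' Minimizes [balanceCost()] over `(log betaKon, log betaKoff)` with a
#' simulated-annealing search adapted to noisy objectives: Gaussian
#' proposals in log space (`config@sigma`), Metropolis acceptance on costs
#' averaged over `config@repeats` simulations, geometric cooling
#' `T_k = t0 * cooling^k`.  With `t0 = 0` the search reduces to stochastic
#' hill-climbing.  The best state visited (not the last accepted one) is
#' returned; non-convergence shows up as a high final cost, never as an
#' error.
#'
#' @inheritParams balanceCost
#' @param start optional length-2 numeric `c(betaKon, betaKoff)` starting
#'   point (default: the gene's current values).
#' @return a list with elements `betaKon`, `betaKoff`, `cost` (best cost
#'   seen) and `trace` (accepted-cost sequence).
#' @export
balanceGene <- function(grn, gene, initialData, config = BalancingConfig(),
                        seed = NULL, start = NULL) {
    stopifnot(is(config, "BalancingConfig"))
    i <- .geneIndex(grn, gene)
    if (!is.null(seed)) set.seed(seed)
    lb <- config@logBetaBounds[1L]
    ub <- config@logBetaBounds[2L]
    if (is.null(start))
        start <- c(grn@kinetics$betaKon[i], grn@kinetics$betaKoff[i])
    x <- pmin(pmax(log(pmax(start, exp(lb))), lb), ub)
    costAt <- function(z)
        balanceCost(grn, gene, initialData, exp(z[1L]), exp(z[2L]), config)
    cur <- costAt(x)
    best <- x
    bestCost <- cur
    trace <- cur
    for (k in seq_len(config@iterations)) {
        temp <- config@t0 * config@cooling^k
        prop <- pmin(pmax(x + rnorm(2L, 0, config@sigma), lb), ub)
        cp <- costAt(prop)
        accept <- cp <= cur ||
            (temp > 0 && runif(1) < exp(-(cp - cur) / temp))
        if (accept) {
            x <- prop
            cur <- cp
            trace <- c(trace, cur)
        }
        if (cp < bestCost) {
            best <- prop
            bestCost <- cp
        }
    }
    list(betaKon = exp(best[1L]), betaKoff = exp(best[2L]),
         cost = bestCost, trace = trace)
}

#' Balance every gene of a GRN
#'
#' Applies [balanceGene()] to each gene independently; results do not depend
#' on the order in which genes are processed (each gene gets its own RNG
#' substream derived from `seed`).
#'
#' @inheritParams balanceCost
#' @param seed optional integer seed; gene i uses `seed + i`.
#' @return a [BalancingResult-class].
#' @seealso [applyBalancing()] to write the fitted values back into the GRN.
#' @export
balanceAll <- function(grn, initialData, config = BalancingConfig(),
                       seed = NULL) {
    res <- lapply(seq_along(grn@genes), function(i)
        balanceGene(grn, grn@genes[i], initialData, config,
                    seed = if (is.null(seed)) NULL else seed + i))
    betas <- data.frame(
        gene = grn@genes,
        betaKon = vapply(res, `[[`, numeric(1), "betaKon"),
        betaKoff = vapply(res, `[[`, numeric(1), "betaKoff"),
        cost = vapply(res, `[[`, numeric(1), "cost"))
    new("BalancingResult", betas = betas,
        traces = setNames(lapply(res, `[[`, "trace"), grn@genes))
}

#' Write balancing results back into a GRN
#'
#' @param grn the [GRN-class] that was balanced.
#' @param result a [BalancingResult-class] from [balanceAll()].
#' @return a copy of `grn` with per-gene `betaKon`/`betaKoff` replaced.
#' @export
applyBalancing <- function(grn, result) {
    stopifnot(is(result, "BalancingResult"))
    idx <- match(result@betas$gene, grn@genes)
    if (anyNA(idx)) stop("balancing result names unknown genes")
    grn@kinetics$betaKon[idx] <- result@betas$betaKon
    grn@kinetics$betaKoff[idx] <- result@betas$betaKoff
    validObject(grn)
    grn
}
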