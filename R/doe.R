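## The design-of-experiment core: screen in-silico perturbations across an
## ensemble, rank them by response entropy, pool predictions, select
## topology-consistent GRNs against observed effects, and quantify
## prediction accuracy.

## One-sided Welch test p-value, robust to (near-)constant samples.
## x = perturbed sample, y = reference; alternative "less" tests down-regulation.
.oneSidedP <- function(x, y, alternative) {
    vx <- var(x)
    vy <- var(y)
    if ((is.na(vx) || vx < .Machine$double.eps) &&
        (is.na(vy) || vy < .Machine$double.eps)) {
        d <- mean(x) - mean(y)
        if (d == 0) return(1)
        ok <- if (alternative == "less") d < 0 else d > 0
        return(if (ok) 0 else 1)
    }
    t.test(x, y, alternative = alternative)$p.value
}

## Build the per-gene two-direction test table for one (pert, ref) pair of
## count matrices, BH-adjusting within each direction family.
.testEffects <- function(pertM, refM, genes, alpha, grnLabel) {
    rows <- do.call(rbind, lapply(c("down", "up"), function(dir) {
        alt <- if (dir == "down") "less" else "greater"
        p <- vapply(genes, function(g)
            .oneSidedP(pertM[, g], refM[, g], alt), numeric(1))
        data.frame(grn = grnLabel, gene = genes, direction = dir,
                   rawP = unname(p), adjustedP = p.adjust(p, "BH"),
                   row.names = NULL)
    }))
    rows$significant <- rows$adjustedP < alpha
    # a gene can only move in one direction: keep the smaller p if both pass
    both <- rows$gene[rows$significant][duplicated(rows$gene[rows$significant])]
    for (g in both) {
        k <- which(rows$gene == g & rows$significant)
        drop <- k[which.max(rows$adjustedP[k])]
        rows$significant[drop] <- FALSE
    }
    rows
}

#' Screen a perturbation across an ensemble
#'
#' For each GRN in the ensemble, simulates a reference (unperturbed) and a
#' perturbed condition to the horizon, then compares the perturbed mRNA
#' counts to the reference per downstream gene with one-sided Welch tests in
#' both directions ('less' for down-regulation, 'greater' for
#' up-regulation).  p-values are Benjamini-Hochberg-adjusted within each
#' (GRN, direction) family and calls are made at `adjustedP < alpha`.  The
#' perturbed target itself is excluded from the calls.
#'
#' Both conditions are initialized from the same `initialData` snapshot, so
#' the ensemble should previously have been balanced ([balanceAll()]) for
#' the reference simulations to stay near that snapshot; common drift
#' cancels in the comparison, but a balanced ensemble gives cleaner calls.
#'
#' @param ensemble a [GRNEnsemble-class].
#' @param perturbation a [Perturbation-class].
#' @param initialData [CountMatrix-class] used to initialize every
#'   simulation.
#' @param nCells cells per condition per GRN (default 200).
#' @param duration simulation horizon in hours (default 100, long enough to
#'   reach the post-perturbation stable state).
#' @param alpha significance threshold on adjusted p-values (default 0.01).
#' @param step rate-refresh interval, hours.
#' @param seed optional integer seed controlling all simulations.
#' @param keepData keep the simulated count matrices in the result (needed
#'   by [pooledPrediction()] reuse).
#' @return an [EffectTable-class].
#' @export
screenPerturbation <- function(ensemble, perturbation, initialData,
                               nCells = 200, duration = 100, alpha = 0.01,
                               step = 0.1, seed = NULL, keepData = FALSE) {
    stopifnot(is(ensemble, "GRNEnsemble"), is(perturbation, "Perturbation"))
    if (!is.null(seed)) set.seed(seed)
    genes <- setdiff(ensemble@grns[[1L]]@genes, perturbation@target)
    if (length(genes) == length(ensemble@grns[[1L]]@genes))
        stop("unknown gene: ", perturbation@target)
    sims <- vector("list", length(ensemble@grns))
    tabs <- vector("list", length(ensemble@grns))
    for (k in seq_along(ensemble@grns)) {
        grn <- ensemble@grns[[k]]
        cellsRef <- initializeCells(grn, initialData, nCells)
        refM <- counts(simulateGRN(grn, cellsRef, duration = duration,
                                   step = step)[[1L]])
        cellsP <- initializeCells(grn, initialData, nCells)
        pertM <- counts(simulateGRN(grn, cellsP, duration = duration,
                                    step = step,
                                    perturbation = perturbation)[[1L]])
        tabs[[k]] <- .testEffects(pertM, refM, genes, alpha,
                                  ensemble@labels[k])
        if (keepData) sims[[k]] <- list(ref = refM, pert = pertM)
    }
    if (keepData) names(sims) <- ensemble@labels
    new("EffectTable", effects = do.call(rbind, tabs),
        perturbation = perturbation, alpha = alpha,
        data = if (keepData) sims else list())
}

#' Summarize a perturbation screen over the ensemble
#'
#' Counts, for every downstream gene, the number of GRNs with a significant
#' expression variation in each direction and the number of GRNs carrying a
#' non-null interaction from the perturbation target to that gene (the
#' maximum attainable response count).  Genes responding in all GRNs or in
#' none are flagged uninformative: such all-or-none responses cannot
#' discriminate between candidates, though they still enter the entropy
#' vector.
#'
#' @param effectTable an [EffectTable-class] from [screenPerturbation()].
#' @param ensemble the screened [GRNEnsemble-class].
#' @return an [EffectSummary-class].
#' @export
summarizeEffects <- function(effectTable, ensemble) {
    stopifnot(is(effectTable, "EffectTable"), is(ensemble, "GRNEnsemble"))
    target <- effectTable@perturbation@target
    genes <- setdiff(ensemble@grns[[1L]]@genes, target)
    eff <- effectTable@effects
    sig <- eff[eff$significant, , drop = FALSE]
    nDown <- vapply(genes, function(g)
        sum(sig$gene == g & sig$direction == "down"), numeric(1))
    nUp <- vapply(genes, function(g)
        sum(sig$gene == g & sig$direction == "up"), numeric(1))
    ti <- match(target, ensemble@grns[[1L]]@genes)
    nInter <- vapply(genes, function(g) {
        gi <- match(g, ensemble@grns[[1L]]@genes)
        sum(vapply(ensemble@grns, function(grn)
            iota(grn@geneInteraction[gi, ti]) != 0L, logical(1)))
    }, numeric(1))
    nVarying <- nDown + nUp
    direction <- ifelse(nVarying == 0, "none",
                 ifelse(nDown > 0 & nUp > 0, "mixed",
                 ifelse(nDown > 0, "down", "up")))
    N <- length(ensemble@grns)
    tab <- data.frame(gene = genes, nDown = unname(nDown), nUp = unname(nUp),
                      nVarying = unname(nVarying),
                      nInteracting = unname(nInter),
                      direction = unname(direction),
                      uninformative = unname(nVarying %in% c(0, N)),
                      row.names = NULL)
    new("EffectSummary", table = tab, ensembleSize = N,
        perturbation = effectTable@perturbation)
}

#' Information carried by a candidate perturbation
#'
#' Shannon entropy (natural log) of the per-gene proportions of ensemble
#' members predicted to respond to the perturbation.  The vector of per-gene
#' response counts (zeros included for unaffected genes, all-or-none genes
#' included as well) is normalized to unit sum; zero entries contribute 0,
#' and an all-zero vector has entropy 0 by convention.  A perturbation that
#' splits the ensemble into many partial response groups scores high and is
#' therefore most informative; one to which every member (or no member)
#' responds identically scores 0.
#'
#' @param x a numeric vector of per-gene response counts, or an
#'   [EffectSummary-class].
#' @param ... unused.
#' @return entropy in nats.
#' @examples
#' perturbationEntropy(c(88, 45, 102, rep(0, 46)))  # 1.0466
#' @rdname perturbationEntropy
#' @export
setMethod("perturbationEntropy", "numeric", function(x, ...) {
    if (any(x < 0) || any(!is.finite(x)))
        stop("counts must be finite and >= 0")
    s <- sum(x)
    if (s == 0) return(0)
    p <- x[x > 0] / s
    -sum(p * log(p))
})

#' @rdname perturbationEntropy
#' @export
setMethod("perturbationEntropy", "EffectSummary", function(x, ...) {
    perturbationEntropy(x@table$nVarying)
})

#' Rank candidate perturbations by entropy
#'
#' Orders perturbation screens by decreasing [perturbationEntropy()];
#' ties are broken by target name for determinism.  The top-ranked
#' perturbation is the most informative experiment to perform next.
#'
#' @param summaries a list of [EffectSummary-class] objects.
#' @return a data.frame with columns `target`, `kind`, `entropy`, ordered
#'   best first.
#' @export
rankPerturbations <- function(summaries) {
    stopifnot(length(summaries) >= 1L)
    df <- data.frame(
        target = vapply(summaries, function(s) s@perturbation@target,
                        character(1)),
        kind = vapply(summaries, function(s) s@perturbation@kind,
                      character(1)),
        entropy = vapply(summaries, perturbationEntropy, numeric(1)),
        row.names = NULL)
    df[order(-df$entropy, df$target), , drop = FALSE]
}

#' Pooled ensemble-wide prediction of perturbation effects
#'
#' Concatenates the simulated cells of all ensemble members per condition
#' into one pooled reference and one pooled perturbed dataset, then runs the
#' same per-gene one-sided tests (both directions, BH-adjusted) as
#' [screenPerturbation()].  This produces the ensemble's average prediction
#' of which genes will respond to the experiment, to be confronted with the
#' real data.
#'
#' @param x an [EffectTable-class] produced with `keepData = TRUE` (reuses
#'   its simulations), or a [GRNEnsemble-class] (simulates afresh).
#' @param ... for the ensemble method, arguments passed to
#'   [screenPerturbation()] (`perturbation`, `initialData`, `nCells`, ...).
#' @return an [EffectTable-class] with a single pooled pseudo-GRN row set.
#' @rdname pooledPrediction
#' @export
setMethod("pooledPrediction", "EffectTable", function(x, ...) {
    if (!length(x@data))
        stop("effect table carries no simulated data; ",
             "rerun screenPerturbation(..., keepData = TRUE)")
    refM <- do.call(rbind, lapply(x@data, `[[`, "ref"))
    pertM <- do.call(rbind, lapply(x@data, `[[`, "pert"))
    genes <- setdiff(colnames(refM), x@perturbation@target)
    new("EffectTable",
        effects = .testEffects(pertM, refM, genes, x@alpha, "pooled"),
        perturbation = x@perturbation, alpha = x@alpha, data = list())
})

#' @rdname pooledPrediction
#' @export
setMethod("pooledPrediction", "GRNEnsemble", function(x, ...) {
    pooledPrediction(screenPerturbation(x, ..., keepData = TRUE))
})

#' Select topology-consistent GRNs against observed effects
#'
#' After performing the chosen knock-out for real, retain the candidate GRNs
#' whose topology can explain at least one observed response: a gene
#' observed down-regulated implicates candidates in which the target
#' activates it (knocking out an activator lowers its targets), a gene
#' observed up-regulated implicates candidates in which the target
#' represses it.  The returned set is the union over observed genes, so
#' adding observations can only grow it.  With `veto = TRUE`, candidates
#' carrying an edge whose sign contradicts an observation are additionally
#' removed.
#'
#' @param ensemble a [GRNEnsemble-class].
#' @param target the knocked-out gene name.
#' @param observed named character vector of observed directions per gene,
#'   values `"down"`, `"up"` or `"none"` (ignored).
#' @param veto stricter mode excluding sign-contradicting candidates
#'   (default `FALSE`).
#' @return sorted integer indices of the retained ensemble members.
#' @export
selectGRNs <- function(ensemble, target, observed, veto = FALSE) {
    stopifnot(is(ensemble, "GRNEnsemble"))
    observed <- observed[observed %in% c("down", "up")]
    if (length(observed) == 0L)
        stop("no observed effects to select on")
    genes <- ensemble@grns[[1L]]@genes
    ti <- match(target, genes)
    if (is.na(ti)) stop("unknown gene: ", target)
    gi <- match(names(observed), genes)
    if (anyNA(gi))
        stop("observed effects name unknown genes: ",
             paste(names(observed)[is.na(gi)], collapse = ", "))
    want <- ifelse(observed == "down", 1L, -1L)
    keep <- vapply(ensemble@grns, function(grn) {
        edge <- iota(grn@geneInteraction[gi, ti])
        ok <- any(edge == want)
        if (veto && any(edge == -want)) ok <- FALSE
        ok
    }, logical(1))
    sort(which(keep))
}

#' Probability of few qualitative prediction errors arising by chance
#'
#' If each of `nGenes` qualitative response predictions (down / up / none)
#' were a blind guess with per-gene error probability `pError`, the number
#' of errors would be binomial; this returns the lower-tail probability of
#' making at most `maxErrors` errors,
#' \eqn{\sum_{k=0}^{E} \binom{n}{k} p^k (1-p)^{n-k}}.  A vanishingly small
#' value means the observed prediction accuracy cannot be luck.
#'
#' @param nGenes number of predicted genes.
#' @param maxErrors maximum number of errors tolerated (0..`nGenes`).
#' @param pError per-gene error probability under blind guessing (2/3 for a
#'   uniform guess over three outcomes).
#' @return a probability.
#' @examples
#' # chance of 48/49 correct qualitative calls under blind guessing
#' predictionAccuracyProbability(49, 2, 2/3)  # 2.0071e-20
#' @export
predictionAccuracyProbability <- function(nGenes, maxErrors, pError) {
    stopifnot(maxErrors >= 0, maxErrors <= nGenes,
              pError >= 0, pError <= 1)
    pbinom(maxErrors, nGenes, pError)
}
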