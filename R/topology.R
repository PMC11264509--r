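## Purely topological analysis of GRN ensembles: sign categorization,
## pairwise difference counts, variance indices, merging.

#' Sign categorization of interaction values
#'
#' Maps an interaction strength to its qualitative category: activation
#' (+1), inhibition (-1) or absence (0).  Vectorized.
#'
#' @param theta finite numeric vector or matrix.
#' @return integer values in \{-1, 0, 1\}, same shape as `theta`.
#' @export
iota <- function(theta) {
    if (any(!is.finite(theta))) stop("interaction values must be finite")
    out <- sign(theta)
    storage.mode(out) <- "integer"
    out
}

.checkSameTopologySupport <- function(a, b) {
    if (!identical(a@genes, b@genes) || !identical(a@stimuli, b@stimuli))
        stop("GRNs must share identical gene and stimulus sets")
}

#' Count qualitative topology differences between two GRNs
#'
#' The number of (target, source) entries whose sign categories ([iota()])
#' differ between the two networks, over gene-gene interactions and -- by
#' default -- stimulus-gene interactions as well.
#'
#' @param a,b [GRN-class] objects over identical gene/stimulus sets.
#' @param includeStimulus count stimulus-to-gene entries too (default
#'   `TRUE`).
#' @return a non-negative integer.
#' @export
pairwiseDifferences <- function(a, b, includeStimulus = TRUE) {
    .checkSameTopologySupport(a, b)
    d <- sum(iota(a@geneInteraction) != iota(b@geneInteraction))
    if (includeStimulus && length(a@stimuli))
        d <- d + sum(iota(a@stimulusInteraction) != iota(b@stimulusInteraction))
    d
}

#' Mean pairwise topology differences in an ensemble
#'
#' Averages [pairwiseDifferences()] over all unordered pairs of ensemble
#' members; 0 for an ensemble with a single member.
#'
#' @param ensemble a [GRNEnsemble-class].
#' @param includeStimulus passed to [pairwiseDifferences()].
#' @return a non-negative number.
#' @export
meanPairwiseDifferences <- function(ensemble, includeStimulus = TRUE) {
    stopifnot(is(ensemble, "GRNEnsemble"))
    n <- length(ensemble@grns)
    if (n < 2L) return(0)
    iotas <- lapply(ensemble@grns, function(g) {
        v <- as.vector(iota(g@geneInteraction))
        if (includeStimulus && length(g@stimuli))
            v <- c(v, as.vector(iota(g@stimulusInteraction)))
        v
    })
    tot <- 0
    for (i in seq_len(n - 1L))
        for (j in seq.int(i + 1L, n))
            tot <- tot + sum(iotas[[i]] != iotas[[j]])
    tot / (n * (n - 1L) / 2L)
}

.varFun <- function(variance) {
    if (variance == "population")
        function(x) mean((x - mean(x))^2)
    else
        function(x) if (length(x) > 1L) var(x) else 0
}

#' Descendants / Ancestors Variance Index
#'
#' For a gene i, `dvi` sums -- over every potential child g -- the
#' across-ensemble variance of the sign category of the interaction from i
#' to g.  It is high when the ensemble disagrees about which genes i
#' regulates (and how), making i a promising knock-out target: its
#' perturbation would elicit many different responses across candidates.
#' `avi` mirrors this for parents (the genes and stimuli regulating i),
#' relevant to perturbations acting upstream of i.
#'
#' Both indices depend only on sign categories, so they are invariant to
#' rescaling all interaction strengths by a positive constant.
#'
#' @param ensemble a [GRNEnsemble-class].
#' @param gene a gene name, or `NULL` (default) for a named vector over all
#'   genes.
#' @param variance `"population"` (divide by N, default) or `"sample"`
#'   (divide by N - 1) across the ensemble.
#' @param includeStimulus for `avi`, include stimulus-to-gene entries
#'   (default `TRUE`).
#' @return a non-negative number, or a named vector over genes.
#' @export
dvi <- function(ensemble, gene = NULL,
                variance = c("population", "sample")) {
    stopifnot(is(ensemble, "GRNEnsemble"))
    variance <- match.arg(variance)
    vf <- .varFun(variance)
    genes <- ensemble@grns[[1L]]@genes
    iotas <- lapply(ensemble@grns, function(g) iota(g@geneInteraction))
    one <- function(gn) {
        i <- match(gn, genes)
        if (is.na(i)) stop("unknown gene: ", gn)
        # outgoing edges of i: column i (entries [g, i] for every child g)
        sum(vapply(seq_along(genes), function(g)
            vf(vapply(iotas, function(m) m[g, i], numeric(1))), numeric(1)))
    }
    if (is.null(gene)) vapply(setNames(genes, genes), one, numeric(1))
    else one(gene)
}

#' @rdname dvi
#' @export
avi <- function(ensemble, gene = NULL,
                variance = c("population", "sample"),
                includeStimulus = TRUE) {
    stopifnot(is(ensemble, "GRNEnsemble"))
    variance <- match.arg(variance)
    vf <- .varFun(variance)
    genes <- ensemble@grns[[1L]]@genes
    stimuli <- ensemble@grns[[1L]]@stimuli
    iotasP <- lapply(ensemble@grns, function(g) iota(g@geneInteraction))
    iotasQ <- lapply(ensemble@grns, function(g) iota(g@stimulusInteraction))
    one <- function(gn) {
        i <- match(gn, genes)
        if (is.na(i)) stop("unknown gene: ", gn)
        # incoming edges of i: row i
        tot <- sum(vapply(seq_along(genes), function(g)
            vf(vapply(iotasP, function(m) m[i, g], numeric(1))), numeric(1)))
        if (includeStimulus && length(stimuli))
            tot <- tot + sum(vapply(seq_along(stimuli), function(s)
                vf(vapply(iotasQ, function(m) m[i, s], numeric(1))),
                numeric(1)))
        tot
    }
    if (is.null(gene)) vapply(setNames(genes, genes), one, numeric(1))
    else one(gene)
}

#' Merge ensemble members into a single GRN
#'
#' Averages the gene-gene and stimulus-gene interaction strengths (zeros
#' included) entrywise over the chosen subset, and likewise averages kinetic
#' parameters and interaction thresholds.  An edge present in any member
#' survives in the merge unless its values cancel exactly; merging identical
#' GRNs returns that GRN.
#'
#' @param ensemble a [GRNEnsemble-class].
#' @param subset member indices to merge (default all).
#' @return a [GRN-class].
#' @export
mergeGRNs <- function(ensemble, subset = seq_along(ensemble@grns)) {
    stopifnot(is(ensemble, "GRNEnsemble"), length(subset) >= 1L)
    members <- ensemble@grns[subset]
    out <- members[[1L]]
    n <- length(members)
    if (n > 1L) {
        out@geneInteraction <-
            Reduce(`+`, lapply(members, slot, "geneInteraction")) / n
        out@stimulusInteraction <-
            Reduce(`+`, lapply(members, slot, "stimulusInteraction")) / n
        kin <- Reduce(`+`, lapply(members, function(g)
            as.matrix(g@kinetics[, .kineticsCols]))) / n
        out@kinetics <- as.data.frame(kin)
        rownames(out@kinetics) <- out@genes
        out@proteinThreshold <-
            Reduce(`+`, lapply(members, slot, "proteinThreshold")) / n
        if (length(out@stimuli))
            out@stimulusThreshold <-
                Reduce(`+`, lapply(members, slot, "stimulusThreshold")) / n
        out@hillExponent <-
            mean(vapply(members, slot, numeric(1), "hillExponent"))
        out@knockedOut <- Reduce(`&`, lapply(members, slot, "knockedOut"))
    }
    validObject(out)
    out
}
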