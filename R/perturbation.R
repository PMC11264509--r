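## Perturbations are pure transformations: they return a modified copy of the
## GRN and never touch the input object.

#' Apply a gene knock-out
#'
#' Silences a gene completely: all interaction entries between the target and
#' its neighbours (incoming and outgoing gene edges, and incoming stimulus
#' edges) are set to 0, its basal adjustments `betaKon`/`betaKoff` are set to
#' 0, and the gene is flagged so that the simulator forces its promoter off
#' and starts it devoid of mRNA and protein.  Idempotent.
#'
#' @param grn a [GRN-class].
#' @param target name of the gene to knock out.
#' @return a modified copy of `grn`.
#' @export
applyKnockout <- function(grn, target) {
    i <- .geneIndex(grn, target)
    grn@geneInteraction[i, ] <- 0
    grn@geneInteraction[, i] <- 0
    if (length(grn@stimuli))
        grn@stimulusInteraction[i, ] <- 0
    grn@kinetics$betaKon[i] <- 0
    grn@kinetics$betaKoff[i] <- 0
    grn@knockedOut[i] <- TRUE
    validObject(grn)
    grn
}

#' Apply a knock-down or over-expression
#'
#' A knock-down multiplies the target's mRNA degradation rate `d0` by
#' `factor` (mimicking siRNA-accelerated decay); an over-expression
#' multiplies its mRNA synthesis rate `s0` (mimicking an expression plasmid).
#' Nothing else changes; `factor = 1` is the identity.
#'
#' @param grn a [GRN-class].
#' @param target gene name.
#' @param factor multiplicative factor, >= 1.
#' @return a modified copy of `grn`.
#' @export
applyKnockdown <- function(grn, target, factor) {
    stopifnot(is.finite(factor), factor > 0)
    i <- .geneIndex(grn, target)
    grn@kinetics$d0[i] <- grn@kinetics$d0[i] * factor
    validObject(grn)
    grn
}

#' @rdname applyKnockdown
#' @export
applyOverexpression <- function(grn, target, factor) {
    stopifnot(is.finite(factor), factor > 0)
    i <- .geneIndex(grn, target)
    grn@kinetics$s0[i] <- grn@kinetics$s0[i] * factor
    validObject(grn)
    grn
}

#' Apply any perturbation
#'
#' Dispatches on the perturbation kind to [applyKnockout()],
#' [applyKnockdown()] or [applyOverexpression()].
#'
#' @param grn a [GRN-class].
#' @param perturbation a [Perturbation-class].
#' @return a modified copy of `grn`.
#' @export
applyPerturbation <- function(grn, perturbation) {
    stopifnot(is(perturbation, "Perturbation"))
    switch(perturbation@kind,
           KO = applyKnockout(grn, perturbation@target),
           KD = applyKnockdown(grn, perturbation@target, perturbation@factor),
           OE = applyOverexpression(grn, perturbation@target,
                                    perturbation@factor))
}
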