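#' Construct an executable GRN
#'
#' Builds a [GRN-class] object from its topology and kinetics, filling in
#' sensible defaults for everything not supplied.  The default kinetics give
#' every gene moderately bursty two-state expression; the default stimulus
#' profile is 0 before t = 0 and 1 afterwards (a differentiation-medium
#' switch at the start of the simulation).
#'
#' @param genes character vector of gene names.
#' @param stimuli character vector of stimulus names (default one stimulus
#'   `"S"`; use `character(0)` for none).
#' @param geneInteraction G x G signed interaction matrix (`[target, source]`;
#'   0 = no edge).  Defaults to no interactions.
#' @param stimulusInteraction G x S signed stimulus-effect matrix.
#' @param kinetics data.frame of per-gene kinetic parameters (see
#'   [GRN-class]); rows are recycled to G if a single row is given.
#' @param proteinThreshold,stimulusThreshold positive interaction thresholds,
#'   recycled to length G / S.
#' @param stimulusProfile list of `cbind(time, level)` matrices, one per
#'   stimulus.
#' @param hillExponent Hill exponent, default 4.
#' @param knockedOut logical knock-out flags, default all `FALSE`.
#'
#' @return a validated [GRN-class] object.
#' @examples
#' grn <- GRN(c("A", "B"))
#' geneInteractions(grn)["B", "A"] <- 2.5  # A activates B
#' @export
GRN <- function(genes,
                stimuli = "S",
                geneInteraction = NULL,
                stimulusInteraction = NULL,
                kinetics = NULL,
                proteinThreshold = 100,
                stimulusThreshold = 0.5,
                stimulusProfile = NULL,
                hillExponent = 4,
                knockedOut = NULL) {
    genes <- as.character(genes)
    stimuli <- as.character(stimuli)
    if (anyDuplicated(genes)) stop("gene names must be unique")
    if (anyDuplicated(stimuli)) stop("stimulus names must be unique")
    G <- length(genes)
    S <- length(stimuli)
    if (is.null(geneInteraction))
        geneInteraction <- matrix(0, G, G)
    if (is.null(stimulusInteraction))
        stimulusInteraction <- matrix(0, G, S)
    dimnames(geneInteraction) <- list(genes, genes)
    dimnames(stimulusInteraction) <- list(genes, if (S) stimuli else NULL)
    if (is.null(kinetics))
        kinetics <- defaultKinetics()
    kinetics <- as.data.frame(kinetics)[, .kineticsCols, drop = FALSE]
    if (nrow(kinetics) == 1L && G > 1L)
        kinetics <- kinetics[rep(1L, G), , drop = FALSE]
    rownames(kinetics) <- genes
    if (is.null(stimulusProfile))
        stimulusProfile <- rep(list(cbind(time = 0, level = 1)), S)
    if (is.null(knockedOut))
        knockedOut <- rep(FALSE, G)
    new("GRN",
        genes = genes, stimuli = stimuli,
        geneInteraction = geneInteraction,
        stimulusInteraction = stimulusInteraction,
        proteinThreshold = setNames(rep_len(proteinThreshold, G), genes),
        stimulusThreshold = setNames(rep_len(stimulusThreshold, max(S, 0)),
                                     if (S) stimuli else NULL),
        stimulusProfile = stimulusProfile,
        kinetics = kinetics,
        hillExponent = hillExponent,
        knockedOut = setNames(as.logical(knockedOut), genes))
}

#' Default per-gene kinetic parameters
#'
#' One row of two-state promoter kinetics used by [GRN()] when none are
#' given: bursty transcription (`s0` = 10 molecules/h, `d0` = 0.5/h), slower
#' protein turnover (`s1` = 1/h, `d1` = 0.1/h), switching-rate bounds
#' `konMin` = 0.1, `konMax` = 2, constant `koff` = 0.5 (burst-frequency
#' regulation), and neutral basal adjustments `betaKon` = `betaKoff` = 1.
#'
#' @return a one-row data.frame with the kinetics columns of [GRN-class].
#' @export
defaultKinetics <- function() {
    data.frame(s0 = 10, d0 = 0.5, s1 = 1, d1 = 0.1,
               konMin = 0.1, konMax = 2, koffMin = 0.5, koffMax = 0.5,
               betaKon = 1, betaKoff = 1)
}

#' Construct a GRN ensemble
#'
#' @param grns list of [GRN-class] objects over identical gene and stimulus
#'   sets.
#' @param labels optional member identifiers (default `grn001`, ...).
#' @return a [GRNEnsemble-class].
#' @export
GRNEnsemble <- function(grns, labels = NULL) {
    if (is(grns, "GRN")) grns <- list(grns)
    if (is.null(labels))
        labels <- sprintf("grn%03d", seq_along(grns))
    new("GRNEnsemble", grns = grns, labels = as.character(labels))
}

#' Construct a count matrix
#'
#' @param counts cells x genes numeric matrix (gene names as column names).
#' @param time acquisition time in hours.
#' @param condition condition label.
#' @return a [CountMatrix-class].
#' @rdname CountMatrix
#' @export
CountMatrix <- function(counts, time = 0, condition = "WT") {
    counts <- as.matrix(counts)
    new("CountMatrix", counts = counts, time = as.numeric(time),
        condition = as.character(condition))
}

#' Construct a perturbation
#'
#' @param target perturbed gene name.
#' @param kind `"KO"`, `"KD"` or `"OE"`.
#' @param factor multiplicative factor for KD (on `d0`) or OE (on `s0`).
#' @return a [Perturbation-class].
#' @seealso [parsePerturbation()] for the `"KO:GENE"` string form.
#' @export
Perturbation <- function(target, kind = c("KO", "KD", "OE"), factor = 1) {
    new("Perturbation", target = as.character(target),
        kind = match.arg(kind), factor = as.numeric(factor))
}

#' Parse a perturbation string
#'
#' Accepts the compact command-line syntax `"KO:GENE"`, `"KD:GENE:2"` or
#' `"OE:GENE:2"`.
#'
#' @param spec a single specification string.
#' @return a [Perturbation-class].
#' @export
parsePerturbation <- function(spec) {
    parts <- strsplit(spec, ":", fixed = TRUE)[[1L]]
    if (length(parts) < 2L || !parts[1L] %in% c("KO", "KD", "OE"))
        stop("perturbation must look like 'KO:GENE', 'KD:GENE:2' or 'OE:GENE:2'")
    factor <- if (length(parts) >= 3L) as.numeric(parts[3L]) else 1
    Perturbation(parts[2L], parts[1L], factor)
}

#' Construct balancing settings
#'
#' @param horizon,nCells,repeats,t0,cooling,iterations,sigma,logBetaBounds,step
#'   see [BalancingConfig-class] for meanings and units.
#' @return a [BalancingConfig-class].
#' @export
BalancingConfig <- function(horizon = 20, nCells = 100, repeats = 3,
                            t0 = 1, cooling = 0.95, iterations = 200,
                            sigma = 0.5, logBetaBounds = c(-6, 4),
                            step = 0.1) {
    new("BalancingConfig", horizon = horizon, nCells = nCells,
        repeats = repeats, t0 = t0, cooling = cooling,
        iterations = iterations, sigma = sigma,
        logBetaBounds = logBetaBounds, step = step)
}

## ---------------------------------------------------------------- accessors

#' Accessors for GRN objects
#'
#' @param x a [GRN-class] (or, for `geneNames`, any object carrying gene
#'   names).
#' @param value replacement value.
#' @return the corresponding slot content.
#' @name grn-accessors
NULL

#' @rdname grn-accessors
#' @export
setMethod("geneNames", "GRN", function(x) x@genes)

#' @rdname grn-accessors
#' @export
setMethod("stimulusNames", "GRN", function(x) x@stimuli)

#' @rdname grn-accessors
#' @export
setMethod("geneInteractions", "GRN", function(x) x@geneInteraction)

#' @rdname grn-accessors
#' @export
setReplaceMethod("geneInteractions", "GRN", function(x, value) {
    x@geneInteraction <- value
    validObject(x)
    x
})

#' @rdname grn-accessors
#' @export
setMethod("stimulusInteractions", "GRN", function(x) x@stimulusInteraction)

#' @rdname grn-accessors
#' @export
setReplaceMethod("stimulusInteractions", "GRN", function(x, value) {
    x@stimulusInteraction <- value
    validObject(x)
    x
})

#' @rdname grn-accessors
#' @export
setMethod("kinetics", "GRN", function(x) x@kinetics)

#' @rdname grn-accessors
#' @export
setReplaceMethod("kinetics", "GRN", function(x, value) {
    x@kinetics <- value
    validObject(x)
    x
})

#' @rdname grn-accessors
#' @export
setMethod("proteinThresholds", "GRN", function(x) x@proteinThreshold)

#' @rdname grn-accessors
#' @export
setMethod("stimulusThresholds", "GRN", function(x) x@stimulusThreshold)

#' @rdname grn-accessors
#' @export
setMethod("hillExponent", "GRN", function(x) x@hillExponent)

#' @rdname grn-accessors
#' @export
setMethod("knockedOut", "GRN", function(x) x@knockedOut)

#' @rdname grn-accessors
#' @export
setMethod("stimulusProfiles", "GRN", function(x) x@stimulusProfile)

#' @rdname grn-accessors
#' @export
setReplaceMethod("stimulusProfiles", "GRN", function(x, value) {
    x@stimulusProfile <- value
    validObject(x)
    x
})

#' @rdname CountMatrix
#' @param object,x a [CountMatrix-class].
#' @export
setMethod("counts", "CountMatrix", function(object) object@counts)

#' @rdname CountMatrix
#' @export
setMethod("geneNames", "CountMatrix", function(x) colnames(x@counts))

#' @rdname CountMatrix
#' @export
setMethod("timeStamp", "CountMatrix", function(x) x@time)

#' @rdname CountMatrix
#' @export
setMethod("conditionLabel", "CountMatrix", function(x) x@condition)

#' Number of members / cells
#'
#' `length` of a [GRNEnsemble-class] is its number of GRNs.
#' @param x a [GRNEnsemble-class].
#' @export
setMethod("length", "GRNEnsemble", function(x) length(x@grns))

#' Extract ensemble members
#'
#' `ens[[i]]` returns the i-th [GRN-class]; `labels(ens)` the member
#' identifiers.
#' @param x a [GRNEnsemble-class].
#' @param i member index.
#' @export
setMethod("[[", "GRNEnsemble", function(x, i) x@grns[[i]])

#' @rdname grn-accessors
#' @param object a [GRNEnsemble-class], for `labels`.
#' @param ... unused.
#' @export
labels.GRNEnsemble <- function(object, ...) object@labels

## ----------------------------------------------------------------- show

setMethod("show", "GRN", function(object) {
    G <- length(object@genes)
    nEdges <- sum(object@geneInteraction != 0)
    nStimEdges <- sum(object@stimulusInteraction != 0)
    cat(sprintf("GRN with %d gene%s, %d stimul%s; %d gene-gene and %d stimulus-gene interaction%s\n",
                G, if (G == 1) "" else "s",
                length(object@stimuli),
                if (length(object@stimuli) == 1) "us" else "i",
                nEdges, nStimEdges,
                if (nEdges + nStimEdges == 1) "" else "s"))
    if (any(object@knockedOut))
        cat("  knocked out:", paste(object@genes[object@knockedOut],
                                    collapse = ", "), "\n")
    cat("  genes:", paste(head(object@genes, 8), collapse = ", "),
        if (G > 8) "..." else "", "\n")
})

setMethod("show", "GRNEnsemble", function(object) {
    cat(sprintf("GRNEnsemble of %d GRNs over %d genes, %d stimuli\n",
                length(object@grns), length(object@grns[[1L]]@genes),
                length(object@grns[[1L]]@stimuli)))
})

setMethod("show", "CountMatrix", function(object) {
    cat(sprintf("CountMatrix: %d cells x %d genes at t = %g h [%s]\n",
                nrow(object@counts), ncol(object@counts), object@time,
                object@condition))
})

setMethod("show", "CellPopulation", function(object) {
    cat(sprintf("CellPopulation of %d cells x %d genes\n",
                nrow(object@mrna), ncol(object@mrna)))
})

setMethod("show", "Perturbation", function(object) {
    cat(sprintf("Perturbation %s:%s%s\n", object@kind, object@target,
                if (object@kind == "KO") ""
                else sprintf(" (factor %g)", object@factor)))
})

setMethod("show", "EffectTable", function(object) {
    sig <- object@effects[object@effects$significant, , drop = FALSE]
    cat(sprintf("EffectTable for %s:%s over %d GRN(s): %d significant call(s) at adjusted p < %g\n",
                object@perturbation@kind, object@perturbation@target,
                length(unique(object@effects$grn)), nrow(sig), object@alpha))
})

setMethod("show", "EffectSummary", function(object) {
    cat(sprintf("EffectSummary for %s:%s over %g GRNs\n",
                object@perturbation@kind, object@perturbation@target,
                object@ensembleSize))
    responding <- object@table[object@table$nVarying > 0, , drop = FALSE]
    if (nrow(responding)) {
        print(responding, row.names = FALSE)
    } else cat("  no responding genes\n")
})

setMethod("show", "MarginalDistance", function(object) {
    cat(sprintf("MarginalDistance over %d genes: total %.4f\n",
                length(object@perGene), object@total))
})

setMethod("show", "BalancingResult", function(object) {
    cat(sprintf("BalancingResult for %d genes; mean final cost %.4f\n",
                nrow(object@betas), mean(object@betas$cost)))
})

## -------------------------------------------------------- interaction model

.geneIndex <- function(grn, gene) {
    if (is.character(gene)) {
        i <- match(gene, grn@genes)
        if (is.na(i)) stop("unknown gene: ", gene)
        i
    } else {
        i <- as.integer(gene)
        if (i < 1L || i > length(grn@genes)) stop("gene index out of range")
        i
    }
}

#' Promoter interaction function
#'
#' Computes the multiplicative interaction term \eqn{\Phi_i(P, Q)} coupling
#' gene i's promoter switching rates to the protein levels of its regulators
#' and to stimulus levels.  Each regulator j contributes a Hill-type factor
#' \deqn{\frac{1 + e^{\theta_{ij}} (P_j/H_j)^\gamma}{1 + (P_j/H_j)^\gamma},}
#' which rises from 1 towards \eqn{e^{\theta}} (activation, \eqn{\theta > 0})
#' or falls towards \eqn{e^{\theta}} (inhibition, \eqn{\theta < 0}) as the
#' regulator crosses its threshold \eqn{H_j}; stimuli contribute identical
#' factors with their own thresholds.  A zero interaction gives a factor of
#' exactly 1, so unconnected genes are unaffected.
#'
#' @param grn a [GRN-class].
#' @param gene target gene (name or index).
#' @param P non-negative protein-level vector, length G.
#' @param Q non-negative stimulus-level vector, length S.
#' @return a single positive number.
#' @examples
#' grn <- GRN(c("A", "B"))
#' interactionPhi(grn, "B", P = c(100, 0), Q = 1)  # no edges: exactly 1
#' @export
interactionPhi <- function(grn, gene, P, Q = numeric(0)) {
    i <- .geneIndex(grn, gene)
    G <- length(grn@genes)
    S <- length(grn@stimuli)
    if (length(P) != G || length(Q) != S)
        stop("P and Q must have lengths ", G, " and ", S)
    if (any(!is.finite(P)) || any(!is.finite(Q)) || any(P < 0) || any(Q < 0))
        stop("P and Q must be finite and non-negative")
    gamma <- grn@hillExponent
    phi <- 1
    if (S) {
        x <- (Q / grn@stimulusThreshold)^gamma
        phi <- prod((1 + exp(grn@stimulusInteraction[i, ]) * x) / (1 + x))
    }
    x <- (P / grn@proteinThreshold)^gamma
    phi * prod((1 + exp(grn@geneInteraction[i, ]) * x) / (1 + x))
}

.boundedRate <- function(rmin, rmax, beta, phi) {
    b <- beta * phi
    if (is.infinite(b)) return(rmax)
    (rmin + rmax * b) / (1 + b)
}

#' Promoter switching rates
#'
#' The promoter activation rate interpolates between its bounds as the
#' interaction term grows:
#' \deqn{k_{on} = \frac{k_{on,min} + k_{on,max}\,\beta_{kon}\,\Phi}{1 + \beta_{kon}\,\Phi},}
#' so `betaKon = 0` pins the gene at `konMin` while a strong activated input
#' drives it towards `konMax`.  `koffRate` is identical with the `koff`
#' bounds and `betaKoff`, sharing the same interaction term \eqn{\Phi}.
#'
#' @inheritParams interactionPhi
#' @return a rate in 1/h, bounded by the gene's `[min, max]` parameters.
#' @export
konRate <- function(grn, gene, P, Q = numeric(0)) {
    i <- .geneIndex(grn, gene)
    k <- grn@kinetics[i, ]
    .boundedRate(k$konMin, k$konMax, k$betaKon,
                 interactionPhi(grn, i, P, Q))
}

#' @rdname konRate
#' @export
koffRate <- function(grn, gene, P, Q = numeric(0)) {
    i <- .geneIndex(grn, gene)
    k <- grn@kinetics[i, ]
    .boundedRate(k$koffMin, k$koffMax, k$betaKoff,
                 interactionPhi(grn, i, P, Q))
}

#' Stimulus levels at a time point
#'
#' Evaluates each stimulus's piecewise-constant profile at time `t`
#' (right-continuous; level 0 before the first breakpoint).
#'
#' @param grn a [GRN-class].
#' @param t time in hours.
#' @return numeric vector of length S.
#' @export
stimulusLevels <- function(grn, t) {
    vapply(grn@stimulusProfile, function(pf) {
        k <- which(pf[, 1L] <= t + 1e-12)
        if (length(k)) pf[max(k), 2L] else 0
    }, numeric(1))
}
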