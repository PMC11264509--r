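## Central S4 classes. All matrices are oriented [target, source]:
## geneInteraction[i, j] is the effect of gene j's protein on gene i's promoter.

.kineticsCols <- c("s0", "d0", "s1", "d1",
                   "konMin", "konMax", "koffMin", "koffMax",
                   "betaKon", "betaKoff")

#' Executable gene regulatory network
#'
#' An executable GRN couples a signed interaction topology to a mechanistic
#' model of stochastic gene expression: each gene has a two-state promoter
#' switching on at rate \eqn{k_{on}} and off at rate \eqn{k_{off}}, both
#' modulated by the protein levels of its regulators and by external stimuli
#' through a product of Hill-type interaction terms.  mRNA and protein follow
#' linear kinetics driven by the promoter state, so the whole system is a
#' piecewise-deterministic Markov process (PDMP).
#'
#' @slot genes character vector of unique gene names (length G).
#' @slot stimuli character vector of unique stimulus names (length S).
#' @slot geneInteraction G x G numeric matrix of signed interaction strengths;
#'   entry `[i, j]` is the effect of gene j's protein on gene i
#'   (0 = no interaction).
#' @slot stimulusInteraction G x S numeric matrix of signed stimulus effects.
#' @slot proteinThreshold positive numeric vector (length G): protein level at
#'   which a regulator reaches half of its maximal effect on a target.
#' @slot stimulusThreshold positive numeric vector (length S): same for
#'   stimuli.
#' @slot stimulusProfile list (length S) of two-column matrices
#'   `cbind(time, level)` describing a piecewise-constant, right-continuous
#'   stimulus level over time; the level before the first breakpoint is 0.
#' @slot kinetics data.frame with one row per gene and columns `s0` (mRNA
#'   synthesis rate when the promoter is on, molecules/h), `d0` (mRNA
#'   degradation rate, 1/h), `s1` (protein synthesis rate per mRNA, 1/h),
#'   `d1` (protein degradation rate, 1/h), `konMin`/`konMax` and
#'   `koffMin`/`koffMax` (bounds of the promoter switching rates, 1/h), and
#'   `betaKon`/`betaKoff` (dimensionless basal-level adjustment factors).
#' @slot hillExponent positive Hill exponent shared by all interactions
#'   (default 4).
#' @slot knockedOut logical vector (length G); `TRUE` marks genes whose
#'   promoter is forced off during simulation (knock-out flag).
#'
#' @seealso [GRN()] for the constructor, [interactionPhi()], [simulateGRN()].
#' @export
setClass("GRN", representation(
    genes = "character",
    stimuli = "character",
    geneInteraction = "matrix",
    stimulusInteraction = "matrix",
    proteinThreshold = "numeric",
    stimulusThreshold = "numeric",
    stimulusProfile = "list",
    kinetics = "data.frame",
    hillExponent = "numeric",
    knockedOut = "logical"
))

setValidity("GRN", function(object) {
    G <- length(object@genes)
    S <- length(object@stimuli)
    msg <- character()
    if (G == 0L) msg <- c(msg, "a GRN needs at least one gene")
    if (anyDuplicated(object@genes)) msg <- c(msg, "gene names must be unique")
    if (anyDuplicated(object@stimuli))
        msg <- c(msg, "stimulus names must be unique")
    if (!all(dim(object@geneInteraction) == c(G, G)))
        msg <- c(msg, "geneInteraction must be a G x G matrix")
    if (!all(dim(object@stimulusInteraction) == c(G, S)))
        msg <- c(msg, "stimulusInteraction must be a G x S matrix")
    if (!all(is.finite(object@geneInteraction)) ||
        !all(is.finite(object@stimulusInteraction)))
        msg <- c(msg, "interaction matrices must be finite")
    if (length(object@proteinThreshold) != G ||
        !all(is.finite(object@proteinThreshold)) ||
        any(object@proteinThreshold <= 0))
        msg <- c(msg, "proteinThreshold must be length G, finite and > 0")
    if (length(object@stimulusThreshold) != S ||
        !all(is.finite(object@stimulusThreshold)) ||
        any(object@stimulusThreshold <= 0))
        msg <- c(msg, "stimulusThreshold must be length S, finite and > 0")
    if (length(object@stimulusProfile) != S) {
        msg <- c(msg, "stimulusProfile must have one entry per stimulus")
    } else {
        for (pf in object@stimulusProfile) {
            if (!is.matrix(pf) || ncol(pf) != 2L || nrow(pf) < 1L ||
                !all(is.finite(pf)) || any(pf[, 2L] < 0) ||
                is.unsorted(pf[, 1L], strictly = TRUE))
                msg <- c(msg, paste("each stimulus profile must be a matrix",
                                    "cbind(time, level) with strictly",
                                    "increasing times and levels >= 0"))
        }
    }
    if (!identical(nrow(object@kinetics), G) ||
        !all(.kineticsCols %in% names(object@kinetics))) {
        msg <- c(msg, sprintf("kinetics must have one row per gene and columns %s",
                              paste(.kineticsCols, collapse = ", ")))
    } else {
        k <- object@kinetics[, .kineticsCols]
        if (!all(vapply(k, is.numeric, logical(1))) ||
            !all(is.finite(as.matrix(k))) || any(as.matrix(k) < 0))
            msg <- c(msg, "all kinetic rates must be finite and >= 0")
        else {
            if (any(k$konMin > k$konMax)) msg <- c(msg, "konMin must be <= konMax")
            if (any(k$koffMin > k$koffMax)) msg <- c(msg, "koffMin must be <= koffMax")
        }
    }
    if (length(object@hillExponent) != 1L || !is.finite(object@hillExponent) ||
        object@hillExponent <= 0)
        msg <- c(msg, "hillExponent must be a single positive number")
    if (length(object@knockedOut) != G)
        msg <- c(msg, "knockedOut must be a logical vector of length G")
    if (length(msg)) msg else TRUE
})

#' Ordered ensemble of candidate GRNs
#'
#' A collection of executable GRNs sharing identical gene and stimulus sets
#' (in the same order), typically produced by an ensemble inference method:
#' all members fit the training data comparably well and differ in a handful
#' of signed edges.  Ensemble order defines GRN indices throughout the
#' package.
#'
#' @slot grns list of [GRN-class] objects.
#' @slot labels character vector of per-member identifiers.
#'
#' @seealso [GRNEnsemble()], [dvi()], [selectGRNs()], [mergeGRNs()].
#' @export
setClass("GRNEnsemble", representation(grns = "list", labels = "character"))

setValidity("GRNEnsemble", function(object) {
    msg <- character()
    if (length(object@grns) == 0L)
        msg <- c(msg, "an ensemble must contain at least one GRN")
    if (!all(vapply(object@grns, is, logical(1), "GRN")))
        msg <- c(msg, "all ensemble members must be GRN objects")
    if (length(object@labels) != length(object@grns))
        msg <- c(msg, "labels must match the number of GRNs")
    if (anyDuplicated(object@labels))
        msg <- c(msg, "ensemble labels must be unique")
    if (length(object@grns) > 1L) {
        g1 <- object@grns[[1L]]
        same <- vapply(object@grns, function(g)
            identical(g@genes, g1@genes) && identical(g@stimuli, g1@stimuli),
            logical(1))
        if (!all(same))
            msg <- c(msg, "all GRNs must share identical gene and stimulus order")
    }
    if (length(msg)) msg else TRUE
})

#' Time-stamped single-cell count matrix
#'
#' mRNA quantities for a population of cells measured (or simulated) at one
#' time point under one condition.  Rows are cells, columns are genes.
#'
#' @slot counts numeric cells x genes matrix, non-negative, with gene names as
#'   column names.
#' @slot time acquisition time in hours.
#' @slot condition condition label, e.g. `"WT"` or `"KO:FNIP1"`.
#'
#' @seealso [CountMatrix()], [readCountMatrix()], [kantorovich1D()].
#' @export
setClass("CountMatrix", representation(
    counts = "matrix", time = "numeric", condition = "character"
))

setValidity("CountMatrix", function(object) {
    msg <- character()
    if (!is.numeric(object@counts) || is.null(colnames(object@counts)))
        msg <- c(msg, "counts must be a numeric matrix with gene column names")
    else if (anyDuplicated(colnames(object@counts)))
        msg <- c(msg, "duplicate gene columns in counts")
    else if (any(!is.finite(object@counts)) || any(object@counts < 0))
        msg <- c(msg, "counts must be finite and >= 0")
    if (length(object@time) != 1L || !is.finite(object@time))
        msg <- c(msg, "time must be a single finite number")
    if (length(object@condition) != 1L)
        msg <- c(msg, "condition must be a single label")
    if (length(msg)) msg else TRUE
})

#' Population of simulated cell states
#'
#' Internal state of a simulated cell population: per-cell binary promoter
#' states and continuous mRNA and protein quantities.
#'
#' @slot promoterState cells x genes 0/1 matrix of promoter states.
#' @slot mrna cells x genes non-negative matrix of mRNA quantities.
#' @slot protein cells x genes non-negative matrix of protein quantities.
#'
#' @seealso [initializeCells()], [simulateGRN()].
#' @export
setClass("CellPopulation", representation(
    promoterState = "matrix", mrna = "matrix", protein = "matrix"
))

setValidity("CellPopulation", function(object) {
    msg <- character()
    d <- dim(object@mrna)
    if (!identical(dim(object@promoterState), d) ||
        !identical(dim(object@protein), d))
        msg <- c(msg, "promoterState, mrna and protein must share dimensions")
    if (!all(object@promoterState %in% c(0, 1)))
        msg <- c(msg, "promoterState entries must be 0 or 1")
    if (any(!is.finite(object@mrna)) || any(object@mrna < 0) ||
        any(!is.finite(object@protein)) || any(object@protein < 0))
        msg <- c(msg, "mrna and protein must be finite and >= 0")
    if (length(msg)) msg else TRUE
})

#' Gene perturbation specification
#'
#' @slot target name of the perturbed gene.
#' @slot kind `"KO"` (knock-out: silence the promoter entirely), `"KD"`
#'   (knock-down: multiply the mRNA degradation rate `d0`) or `"OE"`
#'   (over-expression: multiply the mRNA synthesis rate `s0`).
#' @slot factor multiplicative factor (>= 1) for KD/OE; ignored for KO.
#'
#' @seealso [Perturbation()], [applyPerturbation()].
#' @export
setClass("Perturbation", representation(
    target = "character", kind = "character", factor = "numeric"
))

setValidity("Perturbation", function(object) {
    msg <- character()
    if (length(object@target) != 1L || !nzchar(object@target))
        msg <- c(msg, "target must be a single gene name")
    if (length(object@kind) != 1L || !object@kind %in% c("KO", "KD", "OE"))
        msg <- c(msg, "kind must be one of KO, KD, OE")
    if (length(object@factor) != 1L || !is.finite(object@factor) ||
        object@factor <= 0)
        msg <- c(msg, "factor must be a single positive number")
    if (object@kind %in% c("KD", "OE") && object@factor < 1)
        msg <- c(msg, "KD/OE factor must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Per-GRN, per-gene significance calls for a perturbation screen
#'
#' One row per (GRN, downstream gene, direction): raw and
#' Benjamini-Hochberg-adjusted one-sided p-values comparing perturbed to
#' reference simulated expression, and the resulting significance flag.
#'
#' @slot effects data.frame with columns `grn` (ensemble label), `gene`,
#'   `direction` (`"down"`/`"up"`, relative to reference), `rawP`,
#'   `adjustedP`, `significant`.
#' @slot perturbation the screened [Perturbation-class].
#' @slot alpha significance threshold applied to adjusted p-values.
#' @slot data optional list of per-GRN simulated count matrices
#'   (`ref`/`pert`), kept when `keepData = TRUE` in [screenPerturbation()].
#'
#' @seealso [screenPerturbation()], [summarizeEffects()], [pooledPrediction()].
#' @export
setClass("EffectTable", representation(
    effects = "data.frame", perturbation = "Perturbation",
    alpha = "numeric", data = "list"
))

setValidity("EffectTable", function(object) {
    msg <- character()
    need <- c("grn", "gene", "direction", "rawP", "adjustedP", "significant")
    if (!all(need %in% names(object@effects)))
        msg <- c(msg, sprintf("effects must have columns %s",
                              paste(need, collapse = ", ")))
    else {
        p <- c(object@effects$rawP, object@effects$adjustedP)
        if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
            msg <- c(msg, "p-values must lie in [0, 1]")
        sig <- object@effects[object@effects$significant, , drop = FALSE]
        if (nrow(sig) && anyDuplicated(sig[, c("grn", "gene")]))
            msg <- c(msg, "at most one significant direction per (grn, gene)")
    }
    if (length(object@alpha) != 1L || object@alpha <= 0 || object@alpha >= 1)
        msg <- c(msg, "alpha must be a single value in (0, 1)")
    if (length(msg)) msg else TRUE
})

#' Per-gene response counts for a perturbation screen
#'
#' Summarizes an [EffectTable-class] over the ensemble: for each downstream
#' gene, the number of GRNs with a significant expression variation (split by
#' direction), the number of GRNs carrying a non-null interaction from the
#' perturbation target to that gene (the maximum attainable response count),
#' and an `uninformative` flag for all-or-none responders.
#'
#' @slot table data.frame with columns `gene`, `nDown`, `nUp`, `nVarying`,
#'   `nInteracting`, `direction`, `uninformative`.
#' @slot ensembleSize number of GRNs screened.
#' @slot perturbation the screened [Perturbation-class].
#'
#' @seealso [summarizeEffects()], [perturbationEntropy()],
#'   [rankPerturbations()].
#' @export
setClass("EffectSummary", representation(
    table = "data.frame", ensembleSize = "numeric",
    perturbation = "Perturbation"
))

setValidity("EffectSummary", function(object) {
    msg <- character()
    need <- c("gene", "nDown", "nUp", "nVarying", "nInteracting",
              "direction", "uninformative")
    if (!all(need %in% names(object@table)))
        msg <- c(msg, sprintf("table must have columns %s",
                              paste(need, collapse = ", ")))
    else {
        tb <- object@table
        if (any(tb$nVarying < 0) || any(tb$nVarying != tb$nDown + tb$nUp))
            msg <- c(msg, "nVarying must equal nDown + nUp and be >= 0")
        un <- tb$nVarying %in% c(0, object@ensembleSize)
        if (!identical(as.logical(tb$uninformative), un))
            msg <- c(msg, "uninformative must flag exactly the all-or-none genes")
    }
    if (length(object@ensembleSize) != 1L || object@ensembleSize < 1)
        msg <- c(msg, "ensembleSize must be a single positive number")
    if (length(msg)) msg else TRUE
})

#' Summed per-gene Wasserstein distance between two datasets
#'
#' @slot perGene named non-negative numeric vector of per-gene 1-D
#'   Kantorovich (Wasserstein) distances.
#' @slot total their sum.
#'
#' @seealso [kantorovich1D()].
#' @export
setClass("MarginalDistance", representation(
    perGene = "numeric", total = "numeric"
))

setValidity("MarginalDistance", function(object) {
    msg <- character()
    if (any(object@perGene < 0)) msg <- c(msg, "distances must be >= 0")
    if (length(object@total) != 1L ||
        abs(object@total - sum(object@perGene)) >
            1e-8 * max(1, sum(object@perGene)))
        msg <- c(msg, "total must equal the sum of per-gene distances")
    if (length(msg)) msg else TRUE
})

#' Settings for basal-expression balancing
#'
#' Controls the noisy simulated-annealing search for per-gene
#' (`betaKon`, `betaKoff`) values that hold the initial expression
#' distribution stationary.  See [balanceGene()] for the algorithm.
#'
#' @slot horizon simulation horizon per cost evaluation, hours (default 20).
#' @slot nCells cells per cost evaluation.
#' @slot repeats simulations averaged per cost call (noise reduction).
#' @slot t0 initial annealing temperature.
#' @slot cooling geometric cooling factor per iteration.
#' @slot iterations number of annealing iterations.
#' @slot sigma standard deviation of Gaussian proposals in log-beta space.
#' @slot logBetaBounds length-2 numeric, box bounds on log beta.
#' @slot step promoter-rate refresh interval for the inner simulations, hours.
#'
#' @seealso [BalancingConfig()], [balanceAll()].
#' @export
setClass("BalancingConfig", representation(
    horizon = "numeric", nCells = "numeric", repeats = "numeric",
    t0 = "numeric", cooling = "numeric", iterations = "numeric",
    sigma = "numeric", logBetaBounds = "numeric", step = "numeric"
))

setValidity("BalancingConfig", function(object) {
    msg <- character()
    if (object@horizon <= 0) msg <- c(msg, "horizon must be > 0")
    if (object@nCells < 1) msg <- c(msg, "nCells must be >= 1")
    if (object@repeats < 1) msg <- c(msg, "repeats must be >= 1")
    if (object@t0 < 0) msg <- c(msg, "t0 must be >= 0")
    if (object@cooling <= 0 || object@cooling > 1)
        msg <- c(msg, "cooling must be in (0, 1]")
    if (object@iterations < 1) msg <- c(msg, "iterations must be >= 1")
    if (object@sigma <= 0) msg <- c(msg, "sigma must be > 0")
    if (length(object@logBetaBounds) != 2L ||
        !all(is.finite(object@logBetaBounds)) ||
        object@logBetaBounds[1L] >= object@logBetaBounds[2L])
        msg <- c(msg, "logBetaBounds must be finite and increasing")
    if (object@step <= 0) msg <- c(msg, "step must be > 0")
    if (length(msg)) msg else TRUE
})

#' Result of balancing a whole GRN
#'
#' @slot betas data.frame with columns `gene`, `betaKon`, `betaKoff`, `cost`
#'   (final per-gene distance between horizon and initial marginals).
#' @slot traces named list of accepted-cost sequences, one per gene.
#'
#' @seealso [balanceAll()], [applyBalancing()].
#' @export
setClass("BalancingResult", representation(
    betas = "data.frame", traces = "list"
))

setValidity("BalancingResult", function(object) {
    msg <- character()
    need <- c("gene", "betaKon", "betaKoff", "cost")
    if (!all(need %in% names(object@betas)))
        msg <- c(msg, sprintf("betas must have columns %s",
                              paste(need, collapse = ", ")))
    else if (any(object@betas$betaKon < 0) || any(object@betas$betaKoff < 0) ||
             any(object@betas$cost < 0))
        msg <- c(msg, "betas and costs must be >= 0")
    if (length(msg)) msg else TRUE
})
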