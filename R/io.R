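## Serialization: GRNs and ensembles as JSON, count matrices as TSV/CSV.
##
## GRN JSON schema (field names are snake_case on disk):
##   {"genes":    [{"name", "H_P"}, ...],
##    "stimuli":  [{"name", "H_Q", "profile": [[t, level], ...]}, ...],
##    "gamma":    <Hill exponent>,
##    "theta_P":  [[...]],           # G x G, [target][source]
##    "theta_Q":  [[...]],           # G x S
##    "kinetics": {gene: {"s0","d0","s1","d1","kon_min","kon_max",
##                        "koff_min","koff_max","beta_kon","beta_koff"}},
##    "knocked_out": [gene, ...]}    # optional
## An ensemble is a directory of such files (loaded in lexicographic order)
## or a JSON-lines file (one GRN per line); ordering defines GRN indices.

.kinJsonNames <- c(s0 = "s0", d0 = "d0", s1 = "s1", d1 = "d1",
                   konMin = "kon_min", konMax = "kon_max",
                   koffMin = "koff_min", koffMax = "koff_max",
                   betaKon = "beta_kon", betaKoff = "beta_koff")

.grnToList <- function(grn) {
    kin <- lapply(seq_along(grn@genes), function(i) {
        row <- as.list(grn@kinetics[i, .kineticsCols])
        names(row) <- unname(.kinJsonNames[.kineticsCols])
        row
    })
    names(kin) <- grn@genes
    list(
        genes = lapply(seq_along(grn@genes), function(i)
            list(name = grn@genes[i],
                 H_P = unname(grn@proteinThreshold[i]))),
        stimuli = lapply(seq_along(grn@stimuli), function(s) {
            pf <- grn@stimulusProfile[[s]]
            list(name = grn@stimuli[s],
                 H_Q = unname(grn@stimulusThreshold[s]),
                 profile = lapply(seq_len(nrow(pf)), function(r)
                     unname(pf[r, ])))
        }),
        gamma = grn@hillExponent,
        theta_P = lapply(seq_along(grn@genes), function(r)
            unname(grn@geneInteraction[r, ])),
        theta_Q = lapply(seq_along(grn@genes), function(r)
            unname(grn@stimulusInteraction[r, ])),
        kinetics = kin,
        knocked_out = as.list(grn@genes[grn@knockedOut]))
}

.grnFromList <- function(x, where = "GRN JSON") {
    known <- c("genes", "stimuli", "gamma", "theta_P", "theta_Q",
               "kinetics", "knocked_out")
    extra <- setdiff(names(x), known)
    if (length(extra))
        stop(where, ": unknown field(s) ", paste(extra, collapse = ", "))
    need <- setdiff(known, "knocked_out")
    missing <- setdiff(need, names(x))
    if (length(missing))
        stop(where, ": missing field(s) ", paste(missing, collapse = ", "))
    pick <- function(lst, field, i) {
        if (is.null(lst[[field]]))
            stop(where, ": entry ", i, " lacks field '", field, "'")
        lst[[field]]
    }
    genes <- vapply(x$genes, pick, "", field = "name", i = "genes")
    hP <- vapply(x$genes, function(g)
        as.numeric(pick(g, "H_P", "genes")), numeric(1))
    stimuli <- vapply(x$stimuli, pick, "", field = "name", i = "stimuli")
    hQ <- vapply(x$stimuli, function(s)
        as.numeric(pick(s, "H_Q", "stimuli")), numeric(1))
    profiles <- lapply(x$stimuli, function(s) {
        pf <- pick(s, "profile", "stimuli")
        m <- do.call(rbind, lapply(pf, function(row)
            as.numeric(unlist(row))))
        colnames(m) <- c("time", "level")
        m
    })
    G <- length(genes)
    S <- length(stimuli)
    asMatrix <- function(rows, nc, field) {
        m <- do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r))))
        if (is.null(m)) m <- matrix(0, 0, nc)
        if (!identical(dim(m), c(G, nc)))
            stop(where, ": field '", field, "' has wrong dimensions")
        m
    }
    thetaP <- asMatrix(x$theta_P, G, "theta_P")
    thetaQ <- if (S) asMatrix(x$theta_Q, S, "theta_Q") else matrix(0, G, 0)
    kin <- do.call(rbind, lapply(genes, function(g) {
        row <- x$kinetics[[g]]
        if (is.null(row)) stop(where, ": kinetics missing for gene ", g)
        extraK <- setdiff(names(row), unname(.kinJsonNames))
        if (length(extraK))
            stop(where, ": unknown kinetics field(s) for gene ", g, ": ",
                 paste(extraK, collapse = ", "))
        vals <- vapply(unname(.kinJsonNames[.kineticsCols]), function(f) {
            if (is.null(row[[f]]))
                stop(where, ": kinetics for gene ", g, " lacks '", f, "'")
            as.numeric(row[[f]])
        }, numeric(1))
        as.data.frame(as.list(setNames(vals, .kineticsCols)))
    }))
    ko <- genes %in% unlist(x$knocked_out)
    GRN(genes, stimuli,
        geneInteraction = thetaP, stimulusInteraction = thetaQ,
        kinetics = kin, proteinThreshold = hP, stimulusThreshold = hQ,
        stimulusProfile = profiles, hillExponent = as.numeric(x$gamma),
        knockedOut = ko)
}

#' Read and write GRNs as JSON
#'
#' The on-disk schema stores genes with their protein thresholds, stimuli
#' with thresholds and piecewise-constant profiles, the Hill exponent, the
#' dense gene-gene and stimulus-gene interaction matrices (oriented
#' `[target][source]`; 0 encodes "no interaction") and per-gene kinetics.
#' `readGRN` validates the schema and names the offending field on error;
#' the round trip `writeGRN` then `readGRN` is the identity.
#'
#' @param path file path.
#' @param grn a [GRN-class].
#' @return `readGRN` returns a [GRN-class]; `writeGRN` returns `path`
#'   invisibly.
#' @export
readGRN <- function(path) {
    x <- jsonlite::read_json(path)
    .grnFromList(x, where = basename(path))
}

#' @rdname readGRN
#' @export
writeGRN <- function(grn, path) {
    stopifnot(is(grn, "GRN"))
    jsonlite::write_json(.grnToList(grn), path, auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}

#' Read and write GRN ensembles
#'
#' An ensemble on disk is either a directory of per-GRN JSON files (loaded
#' in lexicographic order, file stems as labels) or a JSON-lines file with
#' one GRN per line.  Ordering defines GRN indices.
#'
#' @param path directory or `.jsonl` file path.
#' @param ensemble a [GRNEnsemble-class].
#' @param format `"dir"` or `"jsonl"` for writing.
#' @return `readEnsemble` returns a [GRNEnsemble-class]; `writeEnsemble`
#'   returns `path` invisibly.
#' @export
readEnsemble <- function(path) {
    if (dir.exists(path)) {
        files <- sort(list.files(path, pattern = "\\.json$",
                                 full.names = TRUE))
        if (!length(files)) stop("no .json files in ", path)
        grns <- lapply(files, readGRN)
        GRNEnsemble(grns, labels = sub("\\.json$", "", basename(files)))
    } else {
        if (!file.exists(path)) stop("no such ensemble: ", path)
        lines <- readLines(path, warn = FALSE)
        lines <- lines[nzchar(trimws(lines))]
        if (!length(lines)) stop("empty ensemble file: ", path)
        grns <- lapply(seq_along(lines), function(i)
            .grnFromList(jsonlite::parse_json(lines[i]),
                         where = sprintf("%s line %d", basename(path), i)))
        GRNEnsemble(grns)
    }
}

#' @rdname readEnsemble
#' @export
writeEnsemble <- function(ensemble, path, format = c("dir", "jsonl")) {
    stopifnot(is(ensemble, "GRNEnsemble"))
    format <- match.arg(format)
    if (format == "dir") {
        dir.create(path, showWarnings = FALSE, recursive = TRUE)
        for (k in seq_along(ensemble@grns))
            writeGRN(ensemble@grns[[k]],
                     file.path(path, paste0(ensemble@labels[k], ".json")))
    } else {
        lines <- vapply(ensemble@grns, function(g)
            as.character(jsonlite::toJSON(.grnToList(g), auto_unbox = TRUE,
                                          digits = NA)), character(1))
        writeLines(lines, path)
    }
    invisible(path)
}

#' Read and write count matrices as TSV/CSV
#'
#' The on-disk layout has one row per cell: a first `cell` identifier
#' column, an optional `time` column (hours; must be constant within a
#' file) and one column per gene.  The separator is inferred from the file
#' extension (`.csv` = comma, otherwise tab).  Values must be non-negative
#' and gene columns unique.  If `genes` is given, columns are checked and
#' reordered to that reference order on load.
#'
#' @param path file path.
#' @param genes optional reference gene order (e.g. `geneNames(grn)`).
#' @param condition condition label for the loaded object.
#' @param cm a [CountMatrix-class].
#' @return `readCountMatrix` returns a [CountMatrix-class];
#'   `writeCountMatrix` returns `path` invisibly.
#' @export
readCountMatrix <- function(path, genes = NULL, condition = "WT") {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- read.delim(path, sep = sep, check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (nrow(df) == 0L || ncol(df) < 2L)
        stop("count matrix file is empty: ", path)
    df[[1L]] <- NULL  # cell identifiers
    tm <- 0
    if ("time" %in% names(df)) {
        tm <- unique(df$time)
        if (length(tm) != 1L)
            stop("count matrix mixes several time stamps: ", path)
        df$time <- NULL
    }
    if (anyDuplicated(names(df)))
        stop("duplicate gene columns in ", path, ": ",
             paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
    m <- as.matrix(df)
    if (!is.numeric(m) || anyNA(m))
        stop("non-numeric or missing values in ", path)
    if (any(m < 0)) stop("negative values in ", path)
    if (!is.null(genes)) {
        missing <- setdiff(genes, colnames(m))
        if (length(missing))
            stop(path, " is missing genes: ",
                 paste(missing, collapse = ", "))
        m <- m[, genes, drop = FALSE]
    }
    CountMatrix(m, time = as.numeric(tm), condition = condition)
}

#' @rdname readCountMatrix
#' @export
writeCountMatrix <- function(cm, path) {
    stopifnot(is(cm, "CountMatrix"))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    m <- counts(cm)
    df <- data.frame(cell = sprintf("cell%04d", seq_len(nrow(m))),
                     time = cm@time, m, check.names = FALSE)
    write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
    invisible(path)
}
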