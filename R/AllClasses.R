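#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Drug-by-ADR incidence container
#'
#' An \code{AdrIncidence} stores a binary drug/adverse-drug-reaction
#' association table as a \linkS4class{SummarizedExperiment} with one assay,
#' \code{"incidence"}, holding ADRs in rows and drugs in columns (drugs are
#' the samples of this experiment). Entry 1 means the drug is known to cause
#' the ADR; the encoding is total, so 0 means "no evidence", never "missing".
#'
#' Use \code{\link{AdrIncidence}} to construct one from a drug-major matrix,
#' and \code{\link{incidenceMatrix}}, \code{\link{drugNames}},
#' \code{\link{adrNames}} to get data back out.
#'
#' @aliases AdrIncidence-class
#' @exportClass AdrIncidence
setClass("AdrIncidence", contains = "SummarizedExperiment")

.validBinaryAssay <- function(m, what) {
    if (!is.numeric(m))
        return(sprintf("%s assay must be numeric 0/1", what))
    bad <- which(!(m == 0 | m == 1), arr.ind = TRUE)
    if (nrow(bad) > 0) {
        i <- bad[1L, 1L]; j <- bad[1L, 2L]
        return(sprintf("non-binary entry %s in %s at row '%s', column '%s'",
                       format(m[i, j]), what,
                       rownames(m)[i] %||% i, colnames(m)[j] %||% j))
    }
    NULL
}

setValidity("AdrIncidence", function(object) {
    msg <- character()
    if (!"incidence" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'incidence' is required")
    else {
        m <- SummarizedExperiment::assay(object, "incidence")
        if (nrow(m) < 1L || ncol(m) < 1L)
            msg <- c(msg, "need at least one drug and one ADR")
        b <- .validBinaryAssay(m, "incidence")
        if (!is.null(b)) msg <- c(msg, b)
    }
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "drug identifiers must be present and unique")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "ADR identifiers must be present and unique")
    if (length(msg)) msg else TRUE
})

#' Construct an AdrIncidence from a drugs-by-ADRs binary matrix
#'
#' @param incidence numeric matrix, drugs in rows and ADRs in columns, with
#'   unique row and column names; entries must be 0 or 1.
#' @return An \linkS4class{AdrIncidence}.
#' @examples
#' m <- cbind(a1 = c(1, 1, 1, 0), a2 = c(0, 1, 0, 1),
#'            a3 = c(0, 0, 1, 1), a4 = c(0, 0, 1, 1))
#' rownames(m) <- paste0("d", 1:4)
#' AdrIncidence(m)
#' @export
AdrIncidence <- function(incidence) {
    incidence <- as.matrix(incidence)
    if (is.null(rownames(incidence)) || is.null(colnames(incidence)))
        stop("incidence matrix must carry drug rownames and ADR colnames")
    new("AdrIncidence",
        SummarizedExperiment(assays = list(incidence = t(incidence))))
}

#' One-hot drug feature blocks
#'
#' A \code{DrugFeatureSet} holds the six binary drug-feature categories
#' (chemical, enzyme, indication, pathway, target, transporter — or any
#' other named blocks) as a single \linkS4class{SummarizedExperiment}:
#' feature columns in rows, drugs in columns, assay \code{"onehot"}, with
#' \code{rowData(x)$block} recording each feature's block of origin so the
#' concatenated representation keeps full column provenance.
#'
#' @aliases DrugFeatureSet-class
#' @exportClass DrugFeatureSet
setClass("DrugFeatureSet", contains = "SummarizedExperiment")

setValidity("DrugFeatureSet", function(object) {
    msg <- character()
    if (!"onehot" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'onehot' is required")
    else {
        b <- .validBinaryAssay(SummarizedExperiment::assay(object, "onehot"),
                               "onehot")
        if (!is.null(b)) msg <- c(msg, b)
    }
    if (!"block" %in% colnames(rowData(object)))
        msg <- c(msg, "rowData must carry a 'block' column")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "drug identifiers must be present and unique")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "feature identifiers must be present and unique")
    if (length(msg)) msg else TRUE
})

#' Construct a DrugFeatureSet from per-block matrices
#'
#' @param blocks named list of binary matrices, one per feature category,
#'   each drugs-by-features with identical drug rownames in identical order.
#' @return A \linkS4class{DrugFeatureSet}; block order follows the list.
#' @export
DrugFeatureSet <- function(blocks) {
    if (length(blocks) < 1L || is.null(names(blocks)) ||
        anyDuplicated(names(blocks)))
        stop("blocks must be a non-empty list with unique names")
    drugs <- rownames(blocks[[1L]])
    if (is.null(drugs))
        stop("feature blocks must carry drug rownames")
    for (nm in names(blocks)) {
        if (!identical(rownames(blocks[[nm]]), drugs))
            stop("block '", nm, "' has a drug ordering different from block '",
                 names(blocks)[1L], "'")
        if (is.null(colnames(blocks[[nm]])))
            colnames(blocks[[nm]]) <- paste0(nm, "_", seq_len(ncol(blocks[[nm]])))
    }
    wide <- do.call(cbind, lapply(blocks, as.matrix))
    colnames(wide) <- unlist(lapply(blocks, colnames), use.names = FALSE)
    if (anyDuplicated(colnames(wide)))
        stop("feature identifiers must be unique across blocks")
    rd <- DataFrame(block = factor(
        rep(names(blocks), vapply(blocks, ncol, 1L)),
        levels = names(blocks)))
    new("DrugFeatureSet",
        SummarizedExperiment(assays = list(onehot = t(wide)), rowData = rd))
}

#' Weighted drug-to-drug network
#'
#' The one-mode projection of the drug/ADR bipartite graph: nodes are drugs,
#' an undirected edge joins two drugs iff they share at least one ADR, its
#' raw weight counts the shared ADRs, and its normalised weight is the
#' min-max rescaling of the raw weight to [0, 1] (set by
#' \code{\link{normalizeEdgeWeights}}, \code{NA} until then).
#'
#' @slot drugIds character vector of node identifiers.
#' @slot edges data.frame with columns \code{from}, \code{to} (integer node
#'   indices, \code{from < to}), \code{weight} (shared-ADR count, >= 1) and
#'   \code{normWeight} (in [0, 1] or \code{NA}).
#' @aliases DrugNetwork-class
#' @exportClass DrugNetwork
setClass("DrugNetwork",
    representation(drugIds = "character", edges = "data.frame"))

setValidity("DrugNetwork", function(object) {
    msg <- character()
    e <- object@edges
    need <- c("from", "to", "weight", "normWeight")
    if (!all(need %in% names(e)))
        return(paste("edges must have columns", paste(need, collapse = ", ")))
    if (anyDuplicated(object@drugIds))
        msg <- c(msg, "drug identifiers must be unique")
    if (nrow(e)) {
        n <- length(object@drugIds)
        if (any(e$from < 1L | e$to > n))
            msg <- c(msg, "edge endpoints out of range")
        if (any(e$from >= e$to))
            msg <- c(msg, "edges must satisfy from < to (no self-edges)")
        if (anyDuplicated(e[, c("from", "to")]))
            msg <- c(msg, "duplicate edges")
        if (any(e$weight < 1))
            msg <- c(msg, "raw weights must be >= 1 (zero-shared pairs are absent)")
        nw <- e$normWeight[!is.na(e$normWeight)]
        if (length(nw) && (min(nw) < 0 || max(nw) > 1))
            msg <- c(msg, "normalised weights must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn DrugNetwork-class pretty-printer
#' @param object a \code{DrugNetwork}
#' @export
setMethod("show", "DrugNetwork", function(object) {
    e <- object@edges
    cat("DrugNetwork with", length(object@drugIds), "drugs and",
        nrow(e), "edges\n")
    if (nrow(e)) {
        cat("  raw shared-ADR weights: ", min(e$weight), "..", max(e$weight),
            "\n", sep = "")
        cat("  normalised weights: ",
            if (all(is.na(e$normWeight))) "unset (run normalizeEdgeWeights)"
            else paste0(format(min(e$normWeight), digits = 3), "..",
                        format(max(e$normWeight), digits = 3)), "\n", sep = "")
    }
    invisible(object)
})

#' Principal component model for one-hot drug features
#'
#' @slot center per-column means removed before projection.
#' @slot rotation orthonormal loading matrix (features x components).
#' @slot varianceRatio explained-variance ratio of the retained components.
#' @slot fullVarianceRatio ratios of the complete spectrum, used by
#'   \code{\link{varianceCurve}} to choose a component count for a target
#'   cumulative variance.
#' @aliases PCAModel-class
#' @exportClass PCAModel
setClass("PCAModel", representation(
    center = "numeric", rotation = "matrix",
    varianceRatio = "numeric", fullVarianceRatio = "numeric"))

setValidity("PCAModel", function(object) {
    k <- ncol(object@rotation)
    if (length(object@varianceRatio) != k)
        return("one variance ratio per retained component required")
    g <- crossprod(object@rotation)
    if (max(abs(g - diag(k))) > 1e-8)
        return("components must be orthonormal")
    if (is.unsorted(rev(object@varianceRatio)))
        return("variance ratios must be non-increasing")
    if (sum(object@fullVarianceRatio) > 1 + 1e-8)
        return("variance ratios must sum to at most 1")
    TRUE
})

#' @describeIn PCAModel-class pretty-printer
#' @param object a \code{PCAModel}
#' @export
setMethod("show", "PCAModel", function(object) {
    cat("PCAModel:", ncol(object@rotation), "components over",
        nrow(object@rotation), "features;",
        sprintf("%.1f%%", 100 * sum(object@varianceRatio)),
        "variance explained\n")
    invisible(object)
})

#' Per-ADR evaluation report
#'
#' Aggregated output of \code{\link{evaluateAdrPrediction}}: per-(ADR,
#' classifier, feature set) cross-validated AUROC/accuracy, classifier-by-
#' ladder mean AUROC, per-ADR improvement from network features,
#' logistic-regression Wald p-value summaries per network feature, and the
#' Pearson correlation matrix of the ten network feature columns.
#'
#' @slot details data.frame, one row per (adr, classifier, featureSet).
#' @slot ladder data.frame of mean AUROC, classifiers in columns.
#' @slot perAdr data.frame with baseline/full AUROC and improvement per ADR.
#' @slot pvalues data.frame of mean/sd Wald p-values per network feature.
#' @slot pvalueMatrix matrix of per-ADR p-values (ADRs x features).
#' @slot featureCorrelation Pearson correlation of network feature columns.
#' @slot config the pipeline configuration used.
#' @aliases AdrEvaluationReport-class
#' @exportClass AdrEvaluationReport
setClass("AdrEvaluationReport", representation(
    details = "data.frame", ladder = "data.frame", perAdr = "data.frame",
    pvalues = "data.frame", pvalueMatrix = "matrix",
    featureCorrelation = "matrix", config = "list"))

#' @describeIn AdrEvaluationReport-class pretty-printer
#' @param object an \code{AdrEvaluationReport}
#' @export
setMethod("show", "AdrEvaluationReport", function(object) {
    cat("AdrEvaluationReport:", nrow(object@perAdr), "ADRs evaluated,",
        nrow(object@ladder), "feature sets,",
        length(unique(object@details$classifier)), "classifier(s)\n")
    cat("mean AUROC by feature set:\n")
    print(round(object@ladder, 3))
    invisible(object)
})
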