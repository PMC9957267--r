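#' Accessors for adrnet containers
#'
#' \code{drugNames} returns the ordered drug identifiers of any adrnet
#' container; \code{adrNames} the ADR identifiers of an
#' \linkS4class{AdrIncidence}; \code{incidenceMatrix} the drug-major binary
#' matrix (drugs in rows, ADRs in columns); \code{blockNames} and
#' \code{blockMatrix} address the feature categories of a
#' \linkS4class{DrugFeatureSet}; \code{edgeTable} returns a
#' \linkS4class{DrugNetwork}'s edges with identifiers resolved.
#'
#' @param x an adrnet container.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("drugNames", function(x) standardGeneric("drugNames"))

#' @rdname accessors
#' @export
setMethod("drugNames", "AdrIncidence", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("drugNames", "DrugFeatureSet", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("drugNames", "DrugNetwork", function(x) x@drugIds)

#' @rdname accessors
#' @export
setGeneric("adrNames", function(x) standardGeneric("adrNames"))

#' @rdname accessors
#' @export
setMethod("adrNames", "AdrIncidence", function(x) rownames(x))

#' @rdname accessors
#' @export
setGeneric("incidenceMatrix", function(x) standardGeneric("incidenceMatrix"))

#' @rdname accessors
#' @export
setMethod("incidenceMatrix", "AdrIncidence", function(x)
    t(SummarizedExperiment::assay(x, "incidence")))

#' @rdname accessors
#' @export
setGeneric("blockNames", function(x) standardGeneric("blockNames"))

#' @rdname accessors
#' @export
setMethod("blockNames", "DrugFeatureSet", function(x)
    levels(SummarizedExperiment::rowData(x)$block))

#' @rdname accessors
#' @param block name of one feature category.
#' @export
setGeneric("blockMatrix", function(x, block) standardGeneric("blockMatrix"))

#' @rdname accessors
#' @export
setMethod("blockMatrix", "DrugFeatureSet", function(x, block) {
    if (!block %in% blockNames(x))
        stop("unknown block '", block, "'")
    keep <- SummarizedExperiment::rowData(x)$block == block
    t(SummarizedExperiment::assay(x, "onehot")[keep, , drop = FALSE])
})

#' Concatenated one-hot drug representation
#'
#' Horizontally concatenates the feature blocks in their fixed block order
#' into one drugs-by-features binary matrix. With the six category widths of
#' a full pharmacological feature set (881 chemical + 111 enzyme +
#' 869 indication + 173 pathway + 786 target + 72 transporter) this yields
#' the 2892-dimensional per-drug representation the downstream PCA consumes.
#' Column provenance (block of origin) is attached as attribute
#' \code{"block"}.
#'
#' @param x a \linkS4class{DrugFeatureSet}.
#' @return binary matrix, drugs in rows; \code{attr(, "block")} maps each
#'   column to its feature category.
#' @export
setGeneric("oneHotMatrix", function(x) standardGeneric("oneHotMatrix"))

#' @rdname oneHotMatrix
#' @export
setMethod("oneHotMatrix", "DrugFeatureSet", function(x) {
    m <- t(SummarizedExperiment::assay(x, "onehot"))
    attr(m, "block") <- as.character(SummarizedExperiment::rowData(x)$block)
    m
})

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setMethod("edgeTable", "DrugNetwork", function(x) {
    e <- x@edges
    data.frame(drug_a = x@drugIds[e$from], drug_b = x@drugIds[e$to],
               raw_weight = e$weight, norm_weight = e$normWeight,
               stringsAsFactors = FALSE)
})

# dense adjacency of the binary graph (0/1) or of the normalised weights
adjacencyMatrix <- function(net, weighted = FALSE) {
    n <- length(net@drugIds)
    A <- matrix(0, n, n, dimnames = list(net@drugIds, net@drugIds))
    e <- net@edges
    if (nrow(e)) {
        w <- if (weighted) e$normWeight else 1
        A[cbind(e$from, e$to)] <- w
        A[cbind(e$to, e$from)] <- w
    }
    A
}

# neighbour index list of the binary graph
adjacencyList <- function(net) {
    n <- length(net@drugIds)
    adj <- rep(list(integer(0)), n)
    e <- net@edges
    if (nrow(e)) {
        both <- c(e$from, e$to)
        nbr <- c(e$to, e$from)
        adj <- unname(split(nbr, factor(both, levels = seq_len(n))))
    }
    adj
}
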