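.delimFor <- function(path, delim = NULL) {
    if (!is.null(delim)) return(delim)
    switch(tolower(tools::file_ext(path)), csv = ",", tsv = "\t", txt = "\t",
           "\t")
}

.readBinaryTable <- function(path, delim, what) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.table(path, sep = delim, header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            quote = "", comment.char = "")
    if (ncol(df) < 2L)
        stop(what, " file must have an identifier column plus data columns")
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
        stop("duplicate row identifier '", ids[duplicated(ids)][1L],
             "' in ", what, " file ", path)
    if (anyDuplicated(colnames(df)[-1L]))
        stop("duplicate column identifier in ", what, " file ", path)
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m))
        stop("non-numeric entries in ", what, " file ", path)
    bad <- which(!(m == 0 | m == 1), arr.ind = TRUE)
    if (nrow(bad) > 0)
        stop("non-binary entry ", format(m[bad[1L, 1L], bad[1L, 2L]]),
             " in ", what, " at row '", ids[bad[1L, 1L]], "', column '",
             colnames(m)[bad[1L, 2L]], "'")
    rownames(m) <- ids
    storage.mode(m) <- "double"
    m
}

#' Read / write a drug-by-ADR incidence matrix
#'
#' Delimited text with a header row of ADR identifiers and a first column of
#' drug identifiers. The delimiter is inferred from the extension
#' (\code{.tsv}/\code{.txt} tab, \code{.csv} comma) unless given. Entries
#' must be exactly 0 or 1; offending cells are reported by row and column
#' identifier. Row and column order are preserved.
#'
#' @param path file path.
#' @param delim optional delimiter override.
#' @return \code{readIncidence}: an \linkS4class{AdrIncidence}.
#' @export
readIncidence <- function(path, delim = NULL) {
    AdrIncidence(.readBinaryTable(path, .delimFor(path, delim), "incidence"))
}

#' @rdname readIncidence
#' @param x an \linkS4class{AdrIncidence}.
#' @export
writeIncidence <- function(x, path, delim = NULL) {
    stopifnot(is(x, "AdrIncidence"))
    .writeMatrix(incidenceMatrix(x), path, .delimFor(path, delim), "drug")
    invisible(path)
}

.writeMatrix <- function(m, path, delim, idName) {
    df <- data.frame(id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1L] <- idName
    utils::write.table(df, path, sep = delim, quote = FALSE,
                       row.names = FALSE)
}

#' Read / write one-hot feature blocks
#'
#' One delimited file per feature category, all sharing the same drug
#' identifier column in the same order.
#'
#' @param paths named character vector of file paths; names are the block
#'   names in their fixed order.
#' @param delim optional delimiter override applied to every file.
#' @return \code{readFeatureBlocks}: a \linkS4class{DrugFeatureSet}.
#' @export
readFeatureBlocks <- function(paths, delim = NULL) {
    if (is.null(names(paths)) || anyDuplicated(names(paths)))
        stop("paths must be uniquely named by block")
    blocks <- lapply(seq_along(paths), function(i)
        .readBinaryTable(paths[[i]], .delimFor(paths[[i]], delim),
                         paste0("feature block '", names(paths)[i], "'")))
    names(blocks) <- names(paths)
    drugs <- rownames(blocks[[1L]])
    for (nm in names(blocks))
        if (!identical(rownames(blocks[[nm]]), drugs))
            stop("feature block '", nm,
                 "' does not share the drug ordering of block '",
                 names(blocks)[1L], "'")
    DrugFeatureSet(blocks)
}

#' @rdname readFeatureBlocks
#' @param x a \linkS4class{DrugFeatureSet}.
#' @param dir output directory; one \code{<block>.tsv} per category.
#' @export
writeFeatureBlocks <- function(x, dir) {
    stopifnot(is(x, "DrugFeatureSet"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- vapply(blockNames(x), function(nm) {
        p <- file.path(dir, paste0(nm, ".tsv"))
        .writeMatrix(blockMatrix(x, nm), p, "\t", "drug")
        p
    }, character(1))
    invisible(paths)
}

#' Write a simulated dataset to a directory
#'
#' Emits \code{incidence.tsv}, one TSV per feature block, and the
#' ground-truth latent assignment as \code{latent_assignment.json} (for
#' diagnostics only; the pipeline never reads it).
#'
#' @param sim a \code{"SyntheticAdrData"} from \code{\link{simulateAdrData}}.
#' @param dir output directory.
#' @export
writeSimulatedData <- function(sim, dir) {
    stopifnot(inherits(sim, "SyntheticAdrData"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeIncidence(sim$incidence, file.path(dir, "incidence.tsv"))
    writeFeatureBlocks(sim$features, dir)
    jsonlite::write_json(sim$latentAssignment,
                         file.path(dir, "latent_assignment.json"))
    invisible(dir)
}

#' Export a drug network as an edge list (and optionally GraphML)
#'
#' @param net a \linkS4class{DrugNetwork}.
#' @param path output TSV with columns drug_a, drug_b, raw_weight,
#'   norm_weight.
#' @export
writeEdgeList <- function(net, path) {
    stopifnot(is(net, "DrugNetwork"))
    utils::write.table(edgeTable(net), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeEdgeList
#' @export
writeGraphML <- function(net, path) {
    stopifnot(is(net, "DrugNetwork"))
    e <- edgeTable(net)
    xml <- c(
        '<?xml version="1.0" encoding="UTF-8"?>',
        '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
        '  <key id="w" for="edge" attr.name="raw_weight" attr.type="double"/>',
        '  <key id="nw" for="edge" attr.name="norm_weight" attr.type="double"/>',
        '  <graph edgedefault="undirected">',
        sprintf('    <node id="%s"/>', net@drugIds),
        sprintf(paste0('    <edge source="%s" target="%s">',
                       '<data key="w">%g</data><data key="nw">%g</data></edge>'),
                e$drug_a, e$drug_b, e$raw_weight, e$norm_weight),
        '  </graph>', '</graphml>')
    writeLines(xml, path)
    invisible(path)
}
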