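#' Project the drug--ADR bipartite graph onto drugs
#'
#' The incidence matrix defines a bipartite graph (drugs on one side, ADRs
#' on the other, unweighted association edges). Projection joins two drugs
#' by an undirected edge iff they share at least one ADR; the edge's raw
#' weight is the number of shared ADRs, i.e. the dot product of the two
#' drugs' incidence rows. Pairs sharing no ADR get no edge. Normalised
#' weights are left unset; see \code{\link{normalizeEdgeWeights}}.
#'
#' @param incidence an \linkS4class{AdrIncidence}.
#' @return a \linkS4class{DrugNetwork}.
#' @examples
#' m <- cbind(a1 = c(1, 1, 1, 0), a2 = c(0, 1, 0, 1),
#'            a3 = c(0, 0, 1, 1), a4 = c(0, 0, 1, 1))
#' rownames(m) <- paste0("d", 1:4)
#' projectToDrugNetwork(AdrIncidence(m)) # 5 edges, (d3,d4) weight 2
#' @export
projectToDrugNetwork <- function(incidence) {
    stopifnot(is(incidence, "AdrIncidence"))
    M <- incidenceMatrix(incidence)
    W <- tcrossprod(M)            # shared-ADR counts for every drug pair
    W[lower.tri(W, diag = TRUE)] <- 0
    idx <- which(W > 0, arr.ind = TRUE)
    edges <- data.frame(from = as.integer(idx[, 1L]),
                        to = as.integer(idx[, 2L]),
                        weight = W[idx],
                        normWeight = rep(NA_real_, nrow(idx)))
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
    new("DrugNetwork", drugIds = rownames(M), edges = edges)
}

#' Min-max normalise edge weights
#'
#' Rescales each raw shared-ADR count X to (X - Xmin) / (Xmax - Xmin) over
#' the network's edges, so the lightest edge maps to 0 and the heaviest to
#' 1. This keeps heavy edges from dominating downstream weighted features
#' while preserving their ordering. When all weights are equal the formula
#' is undefined (Xmax = Xmin); every edge then gets weight 1, preserving the
#' network rather than annihilating it.
#'
#' @param net a \linkS4class{DrugNetwork} with at least one edge.
#' @return the network with \code{normWeight} filled in.
#' @export
normalizeEdgeWeights <- function(net) {
    stopifnot(is(net, "DrugNetwork"))
    w <- net@edges$weight
    if (length(w) == 0L) stop("cannot normalise an edgeless network")
    rng <- range(w)
    net@edges$normWeight <-
        if (rng[1L] == rng[2L]) rep(1, length(w))
        else (w - rng[1L]) / (rng[2L] - rng[1L])
    validObject(net)
    net
}

#' Global network statistics
#'
#' Node and edge counts, average degree (2E/N), density (2E/(N(N-1))),
#' diameter and average shortest-path length over all ordered reachable
#' pairs (unweighted), and mean local clustering coefficient (nodes of
#' degree < 2 contribute 0). On a disconnected network the path statistics
#' are computed on the largest connected component and the summary is
#' flagged (\code{connected = FALSE}).
#'
#' @param net a \linkS4class{DrugNetwork} with at least one node.
#' @return named list with fields \code{nodeCount}, \code{edgeCount},
#'   \code{averageDegree}, \code{diameter}, \code{averagePathLength},
#'   \code{density}, \code{averageClustering}, \code{connected}.
#' @export
networkSummary <- function(net) {
    stopifnot(is(net, "DrugNetwork"))
    n <- length(net@drugIds)
    if (n == 0L) stop("empty network")
    e <- nrow(net@edges)
    adj <- adjacencyList(net)
    comp <- componentMembership(adj)
    connected <- max(comp) == 1L
    largest <- which(comp == which.max(tabulate(comp)))
    dists <- c()
    diam <- 0
    apl <- NA_real_
    if (length(largest) > 1L) {
        total <- 0; npairs <- 0
        for (s in largest) {
            d <- bfsDistances(adj, s)[largest]
            d <- d[is.finite(d) & d > 0]
            total <- total + sum(d)
            npairs <- npairs + length(d)
            diam <- max(diam, if (length(d)) max(d) else 0)
        }
        apl <- total / npairs
    }
    list(nodeCount = n, edgeCount = e,
         averageDegree = 2 * e / n,
         diameter = as.integer(diam),
         averagePathLength = apl,
         density = if (n > 1L) 2 * e / (n * (n - 1)) else 0,
         averageClustering = mean(clusteringCoefficient(net)),
         connected = connected)
}
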