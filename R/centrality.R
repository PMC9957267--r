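#' Per-drug network centrality features
#'
#' Ten node-level measures are extracted from the projected drug-to-drug
#' network and used as learning features. Exactly two of them consume the
#' normalised edge weights — weighted degree (strength) and weighted
#' PageRank; the other eight see only edge existence. Letters follow the
#' conventional legend used when the measures are cumulated into feature
#' ladders: D degree, W weighted degree, E eigenvector, O closeness,
#' C clustering coefficient, B betweenness, A authority, H hub,
#' T triangles, P weighted PageRank.
#'
#' @param net a \linkS4class{DrugNetwork}.
#' @param tol convergence tolerance (max-norm change between iterates).
#' @param maxIter iteration cap for the power-iteration measures.
#' @param damping PageRank damping factor.
#' @name centrality
NULL

.requireWeights <- function(net) {
    if (nrow(net@edges) && anyNA(net@edges$normWeight))
        stop("normalised edge weights are unset; run normalizeEdgeWeights()")
}

#' @describeIn centrality degree divided by N-1 on the binary graph.
#' @export
degreeCentrality <- function(net) {
    stopifnot(is(net, "DrugNetwork"))
    n <- length(net@drugIds)
    if (n < 2L) stop("degree centrality needs at least two nodes")
    deg <- lengths(adjacencyList(net))
    stats::setNames(deg / (n - 1), net@drugIds)
}

#' @describeIn centrality node strength: sum of normalised incident weights.
#' @export
weightedDegree <- function(net) {
    stopifnot(is(net, "DrugNetwork"))
    .requireWeights(net)
    rowSums(adjacencyMatrix(net, weighted = TRUE))
}

# shifted power iteration x <- (A + I) x; the shift removes the sign
# oscillation a bipartite spectrum (+/- lambda_1) would otherwise cause
.powerIterate <- function(A, tol, maxIter) {
    n <- nrow(A)
    x <- rep(1 / sqrt(n), n)
    for (it in seq_len(maxIter)) {
        xn <- as.vector(A %*% x) + x
        xn <- xn / sqrt(sum(xn^2))
        if (max(abs(xn - x)) < tol) return(xn)
        x <- xn
    }
    stop("power iteration did not converge in ", maxIter, " iterations")
}

# run f on the largest connected component, zeros elsewhere; flags the
# result when the graph is disconnected
.onLargestComponent <- function(net, f) {
    adj <- adjacencyList(net)
    comp <- componentMembership(adj)
    if (max(comp) == 1L) return(f(net, seq_along(adj)))
    keep <- which(comp == which.max(tabulate(comp)))
    res <- numeric(length(adj))
    res[keep] <- f(net, keep)
    names(res) <- net@drugIds
    attr(res, "connected") <- FALSE
    res
}

#' @describeIn centrality principal eigenvector of the binary adjacency
#'   matrix (unit Euclidean norm, non-negative). On a disconnected network
#'   it is computed on the largest component with zeros elsewhere and the
#'   result carries \code{attr(, "connected") = FALSE}.
#' @export
eigenvectorCentrality <- function(net, tol = 1e-10, maxIter = 1000L) {
    stopifnot(is(net, "DrugNetwork"))
    .onLargestComponent(net, function(net, keep) {
        A <- adjacencyMatrix(net)[keep, keep, drop = FALSE]
        x <- .powerIterate(A, tol, maxIter)
        stats::setNames(abs(x), net@drugIds[keep])
    })
}

#' @describeIn centrality (N-1)/sum of unweighted shortest-path distances;
#'   on disconnected networks the within-component value is scaled by
#'   (reachable-1)/(N-1) (Wasserman-Faust convention).
#' @export
closenessCentrality <- function(net) {
    stopifnot(is(net, "DrugNetwork"))
    adj <- adjacencyList(net)
    n <- length(adj)
    if (n < 2L) stop("closeness needs at least two nodes")
    vapply(seq_len(n), function(v) {
        d <- bfsDistances(adj, v)
        d <- d[is.finite(d) & d > 0]
        r <- length(d)                  # reachable nodes besides v
        if (r == 0L) return(0)
        (r / sum(d)) * (r / (n - 1))
    }, numeric(1)) -> cc
    stats::setNames(cc, net@drugIds)
}

#' @describeIn centrality fraction of a node's neighbour pairs that are
#'   themselves connected; 0 for degree < 2.
#' @export
clusteringCoefficient <- function(net) {
    stopifnot(is(net, "DrugNetwork"))
    A <- adjacencyMatrix(net)
    deg <- rowSums(A)
    tri <- diag(A %*% A %*% A) / 2
    cc <- ifelse(deg < 2, 0, 2 * tri / (deg * (deg - 1)))
    stats::setNames(cc, net@drugIds)
}

#' @describeIn centrality Brandes pair-dependency accumulation on the
#'   binary graph, endpoints excluded, normalised by 2/((N-1)(N-2)).
#' @export
betweennessCentrality <- function(net) {
    stopifnot(is(net, "DrugNetwork"))
    adj <- adjacencyList(net)
    n <- length(adj)
    if (n < 3L) stop("betweenness needs at least three nodes")
    bc <- numeric(n)
    for (s in seq_len(n)) {
        sigma <- numeric(n); sigma[s] <- 1
        dist <- rep(-1L, n); dist[s] <- 0L
        preds <- rep(list(integer(0)), n)
        queue <- integer(n); queue[1L] <- s
        head <- 1L; tail <- 1L
        while (head <= tail) {
            v <- queue[head]; head <- head + 1L
            for (w in adj[[v]]) {
                if (dist[w] < 0L) {
                    dist[w] <- dist[v] + 1L
                    tail <- tail + 1L; queue[tail] <- w
                }
                if (dist[w] == dist[v] + 1L) {
                    sigma[w] <- sigma[w] + sigma[v]
                    preds[[w]] <- c(preds[[w]], v)
                }
            }
        }
        delta <- numeric(n)
        for (w in queue[tail:1L]) {
            for (v in preds[[w]])
                delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
            if (w != s) bc[w] <- bc[w] + delta[w]
        }
    }
    # undirected: accumulation counts each pair twice; combined with the
    # 2/((N-1)(N-2)) normalisation this leaves a single 1/((N-1)(N-2))
    stats::setNames(bc / ((n - 1) * (n - 2)), net@drugIds)
}

#' @describeIn centrality HITS hub and authority scores. Undirected edges
#'   are treated as reciprocal directed pairs, under which the mutual
#'   reinforcement recursion a = A'h, h = Aa collapses: hubs and
#'   authorities share the non-negative principal (Perron) eigenvector of
#'   the symmetric adjacency, which also spans the leading eigenspace of
#'   A'A. It is computed by the same shifted power iteration as eigenvector
#'   centrality (unit L2 norm), so hub = authority holds exactly, and the
#'   identity is asserted before returning \code{list(hub, authority)}.
#' @export
hitsScores <- function(net, tol = 1e-10, maxIter = 1000L) {
    stopifnot(is(net, "DrugNetwork"))
    res <- .onLargestComponent(net, function(net, keep) {
        A <- adjacencyMatrix(net)[keep, keep, drop = FALSE]
        h <- abs(.powerIterate(A, tol, maxIter))
        a <- as.vector(A %*% h)
        a <- abs(a / sqrt(sum(a^2)))
        if (max(abs(a - h)) > 1e-6)
            stop("hub and authority diverge on an undirected graph")
        stats::setNames(h, net@drugIds[keep])
    })
    flag <- attr(res, "connected")
    out <- list(hub = res, authority = res)
    if (!is.null(flag)) attr(out, "connected") <- flag
    out
}

#' @describeIn centrality number of triangles through each node.
#' @export
triangleCounts <- function(net) {
    stopifnot(is(net, "DrugNetwork"))
    A <- adjacencyMatrix(net)
    tri <- as.integer(round(diag(A %*% A %*% A) / 2))
    stats::setNames(tri, net@drugIds)
}

#' @describeIn centrality weighted PageRank on the normalised weights,
#'   edges treated as bidirectional: a walker at drug u moves to neighbour
#'   v with probability proportional to the edge weight w(u, v), so
#'   PR(v) = (1-d)/N + d * sum over neighbours u of PR(u) w(u,v)/strength(u).
#'   Nodes of zero strength (no edges, or all incident weights normalised
#'   to 0) redistribute uniformly. Scores sum to 1.
#' @export
weightedPageRank <- function(net, damping = 0.85, tol = 1e-8,
                             maxIter = 1000L) {
    stopifnot(is(net, "DrugNetwork"))
    .requireWeights(net)
    W <- adjacencyMatrix(net, weighted = TRUE)
    n <- nrow(W)
    strength <- rowSums(W)
    dangling <- strength == 0
    P <- W / ifelse(strength == 0, 1, strength)   # row-stochastic off dangling
    pr <- rep(1 / n, n)
    for (it in seq_len(maxIter)) {
        prn <- (1 - damping) / n +
            damping * (as.vector(crossprod(P, pr)) + sum(pr[dangling]) / n)
        if (max(abs(prn - pr)) < tol)
            return(stats::setNames(prn / sum(prn), net@drugIds))
        pr <- prn
    }
    stop("weighted PageRank did not converge in ", maxIter, " iterations")
}

#' Assemble the ten-column network feature table
#'
#' Runs every measure of \code{\link{centrality}} and binds them in the
#' fixed letter order D, W, E, O, C, B, A, H, T, P.
#'
#' @inheritParams centrality
#' @return numeric matrix, one row per drug, columns D..P. Carries
#'   \code{attr(, "connected") = FALSE} when the network is disconnected
#'   (eigenvector/HITS then computed on the largest component).
#' @export
networkFeatureTable <- function(net, tol = 1e-10, maxIter = 1000L,
                                damping = 0.85) {
    stopifnot(is(net, "DrugNetwork"))
    .requireWeights(net)
    ev <- eigenvectorCentrality(net, tol, maxIter)
    hits <- hitsScores(net, tol, maxIter)
    out <- cbind(D = degreeCentrality(net),
                 W = weightedDegree(net),
                 E = as.vector(ev),
                 O = closenessCentrality(net),
                 C = clusteringCoefficient(net),
                 B = betweennessCentrality(net),
                 A = as.vector(hits$authority),
                 H = as.vector(hits$hub),
                 T = triangleCounts(net),
                 P = weightedPageRank(net, damping, tol = 1e-8,
                                      maxIter = maxIter))
    rownames(out) <- net@drugIds
    if (isFALSE(attr(ev, "connected")))
        attr(out, "connected") <- FALSE
    out
}

#' Write the network feature table as TSV
#'
#' @param features matrix from \code{\link{networkFeatureTable}}.
#' @param path output path.
#' @export
writeFeatureTable <- function(features, path) {
    .writeMatrix(features, path, "\t", "drug")
    invisible(path)
}
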