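# the four-drug, four-ADR worked example: d1={a1}, d2={a1,a2},
# d3={a1,a3,a4}, d4={a2,a3,a4}
workedIncidence <- function() {
    m <- cbind(a1 = c(1, 1, 1, 0), a2 = c(0, 1, 0, 1),
               a3 = c(0, 0, 1, 1), a4 = c(0, 0, 1, 1))
    rownames(m) <- paste0("d", 1:4)
    AdrIncidence(m)
}

workedNetwork <- function() {
    normalizeEdgeWeights(projectToDrugNetwork(workedIncidence()))
}

randomIncidence <- function(nDrugs, nAdrs, p = 0.3, seed = 1) {
    set.seed(seed)
    m <- matrix(as.numeric(runif(nDrugs * nAdrs) < p), nDrugs, nAdrs,
                dimnames = list(sprintf("d%02d", seq_len(nDrugs)),
                                sprintf("a%02d", seq_len(nAdrs))))
    AdrIncidence(m)
}

# build a DrugNetwork directly from a binary adjacency matrix, assigning
# random integer raw weights, and min-max normalise
netFromAdjacency <- function(A, seed = 1) {
    n <- nrow(A)
    idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
    set.seed(seed)
    edges <- data.frame(from = as.integer(idx[, 1]), to = as.integer(idx[, 2]),
                        weight = sample(1:5, nrow(idx), replace = TRUE),
                        normWeight = NA_real_)
    edges <- edges[order(edges$from, edges$to), ]
    rownames(edges) <- NULL
    net <- new("DrugNetwork", drugIds = sprintf("n%02d", seq_len(n)),
               edges = edges)
    normalizeEdgeWeights(net)
}

# connected Erdos-Renyi test graph as a DrugNetwork with random weights
randomConnectedNetwork <- function(n, p, seed) {
    set.seed(seed)
    repeat {
        A <- matrix(runif(n * n) < p, n, n)
        A[lower.tri(A, diag = TRUE)] <- FALSE
        A <- A | t(A)
        mode(A) <- "numeric"
        if (sum(A) == 0) next
        g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
        if (igraph::is_connected(g)) break
    }
    netFromAdjacency(A, seed = seed + 1)
}

adjacencyOf <- function(net, weighted = FALSE) {
    adrnet:::adjacencyMatrix(net, weighted = weighted)
}

igraphOf <- function(net) {
    igraph::graph_from_adjacency_matrix(adjacencyOf(net),
                                        mode = "undirected")
}

# dense linear-system PageRank oracle: solve (I - dM) x = (1-d)/n with
# transition matrix column M[, u] = w(u, .) / strength(u), dangling
# columns uniform
pagerankOracle <- function(W, d = 0.85) {
    n <- nrow(W)
    s <- rowSums(W)
    P <- W / ifelse(s == 0, 1, s)
    P[s == 0, ] <- 0
    M <- t(P)
    M[, s == 0] <- 1 / n
    x <- solve(diag(n) - d * M, rep((1 - d) / n, n))
    unname(x / sum(x))
}

# brute-force pairwise Mann-Whitney AUROC
aurocBruteForce <- function(scores, labels) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    if (!length(pos) || !length(neg)) return(NA_real_)
    total <- 0
    for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
    total / (length(pos) * length(neg))
}

smallSimulation <- function(seed = 11) {
    simulateAdrData(simulationConfig(
        nDrugs = 80, nAdrs = 40, blockWidths = rep(10, 6), nLatent = 8,
        seed = seed))
}
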