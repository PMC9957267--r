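`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a temporary RNG state so library code never clobbers
# the caller's random stream.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Area under the ROC curve by the rank statistic
#'
#' Computes AUROC as the Mann-Whitney probability that a randomly chosen
#' positive outscores a randomly chosen negative, with tied scores counting
#' one half. Equivalent to trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric predicted scores (any monotone scale).
#' @param labels binary labels (0/1 or logical), 1 = positive.
#' @return AUROC in [0, 1], or \code{NA} if only one class is present.
#' @examples
#' aurocScore(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)) # 1
#' aurocScore(rep(0.5, 4), c(1, 1, 0, 0))           # 0.5 (all tied)
#' @export
aurocScore <- function(scores, labels) {
    labels <- as.integer(as.logical(labels) | labels == 1)
    stopifnot(length(scores) == length(labels))
    n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
    if (n1 == 0L || n0 == 0L) return(NA_real_)
    r <- rank(scores, ties.method = "average")
    (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

accuracyScore <- function(scores, labels, threshold = 0.5) {
    mean((scores > threshold) == (labels == 1))
}

# breadth-first distances from one source over an adjacency list;
# unreachable nodes get Inf
bfsDistances <- function(adjList, source) {
    n <- length(adjList)
    dist <- rep(Inf, n)
    dist[source] <- 0
    frontier <- source
    d <- 0
    while (length(frontier)) {
        d <- d + 1
        nxt <- unique(unlist(adjList[frontier], use.names = FALSE))
        nxt <- nxt[is.infinite(dist[nxt])]
        dist[nxt] <- d
        frontier <- nxt
    }
    dist
}

# connected components of an undirected adjacency list; integer membership
componentMembership <- function(adjList) {
    n <- length(adjList)
    comp <- integer(n)
    k <- 0L
    for (s in seq_len(n)) {
        if (comp[s] != 0L) next
        k <- k + 1L
        frontier <- s
        comp[s] <- k
        while (length(frontier)) {
            nxt <- unique(unlist(adjList[frontier], use.names = FALSE))
            nxt <- nxt[comp[nxt] == 0L]
            comp[nxt] <- k
            frontier <- nxt
        }
    }
    comp
}
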