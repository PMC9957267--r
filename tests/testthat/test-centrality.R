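# reference values for the worked 4-drug network are hand-derivable:
# adjacency d1-d2, d1-d3, d2-d3, d2-d4, d3-d4; normalised weights put 1 on
# (d3,d4) and 0 elsewhere

test_that("degree, closeness, clustering and triangles on the worked graph", {
    net <- workedNetwork()
    expect_equal(degreeCentrality(net),
                 c(d1 = 2 / 3, d2 = 1, d3 = 1, d4 = 2 / 3))
    expect_equal(closenessCentrality(net),
                 c(d1 = 3 / 4, d2 = 1, d3 = 1, d4 = 3 / 4))
    cc <- clusteringCoefficient(net)
    expect_equal(cc[["d1"]], 1)       # neighbours d2, d3 are connected
    expect_equal(cc[["d2"]], 2 / 3)
    expect_identical(triangleCounts(net),
                     c(d1 = 1L, d2 = 2L, d3 = 2L, d4 = 1L))
})

test_that("weighted degree sums normalised incident weights", {
    net <- workedNetwork()
    expect_equal(weightedDegree(net), c(d1 = 0, d2 = 0, d3 = 1, d4 = 1))

    raw <- projectToDrugNetwork(workedIncidence())
    expect_error(weightedDegree(raw), "unset")
})

test_that("eigenvector centrality matches the dense eigendecomposition", {
    net <- workedNetwork()
    A <- adjacencyOf(net)
    ref <- abs(eigen(A, symmetric = TRUE)$vectors[, 1])
    expect_equal(unname(eigenvectorCentrality(net)), ref, tolerance = 1e-8)

    # K3: full symmetry
    K3 <- matrix(1, 3, 3); diag(K3) <- 0
    expect_equal(unname(eigenvectorCentrality(netFromAdjacency(K3))),
                 rep(1 / sqrt(3), 3), tolerance = 1e-8)

    # P3: middle node dominates by Perron-Frobenius
    P3 <- matrix(0, 3, 3); P3[1, 2] <- P3[2, 3] <- 1; P3 <- P3 + t(P3)
    ev <- eigenvectorCentrality(netFromAdjacency(P3))
    expect_gt(ev[2], ev[1])
    expect_gt(ev[2], ev[3])
})

test_that("HITS hub equals authority and matches the A^2 eigenvector", {
    net <- workedNetwork()
    h <- hitsScores(net)
    expect_equal(h$hub, h$authority)
    ref <- abs(eigen(crossprod(adjacencyOf(net)), symmetric = TRUE)$vectors[, 1])
    expect_equal(unname(h$hub), ref, tolerance = 1e-6)

    K3 <- matrix(1, 3, 3); diag(K3) <- 0
    expect_equal(unname(hitsScores(netFromAdjacency(K3))$hub),
                 rep(1 / sqrt(3), 3), tolerance = 1e-8)
})

test_that("betweenness matches brute-force shortest-path counting", {
    # P3: middle node covers the single (end, end) geodesic exactly
    P3 <- matrix(0, 3, 3); P3[1, 2] <- P3[2, 3] <- 1; P3 <- P3 + t(P3)
    expect_equal(unname(betweennessCentrality(netFromAdjacency(P3))),
                 c(0, 1, 0))

    K4 <- matrix(1, 4, 4); diag(K4) <- 0
    expect_equal(unname(betweennessCentrality(netFromAdjacency(K4))),
                 rep(0, 4))

    net <- randomConnectedNetwork(8, 0.35, seed = 3)
    ref <- igraph::betweenness(igraphOf(net), normalized = TRUE)
    expect_equal(unname(betweennessCentrality(net)), unname(ref),
                 tolerance = 1e-10)
})

test_that("weighted PageRank conserves mass and solves the linear system", {
    net <- randomConnectedNetwork(5, 0.6, seed = 21)
    pr <- weightedPageRank(net)
    expect_equal(sum(pr), 1, tolerance = 1e-9)
    expect_equal(unname(pr),
                 pagerankOracle(adjacencyOf(net, weighted = TRUE)),
                 tolerance = 1e-6)

    K3 <- matrix(1, 3, 3); diag(K3) <- 0
    k3net <- netFromAdjacency(K3)
    k3net@edges$normWeight <- 1      # equal weights: full symmetry
    expect_equal(unname(weightedPageRank(k3net)),
                 rep(1 / 3, 3), tolerance = 1e-8)
})

test_that("all ten measures match reference implementations on random graphs", {
    for (i in 1:50) {
        n <- sample(5:30, 1)
        net <- randomConnectedNetwork(n, runif(1, 0.25, 0.6), seed = 1000 + i)
        g <- igraphOf(net)
        A <- adjacencyOf(net)
        W <- adjacencyOf(net, weighted = TRUE)
        ft <- networkFeatureTable(net)

        expect_equal(unname(ft[, "D"]),
                     unname(igraph::degree(g)) / (n - 1), tolerance = 1e-12)
        ew <- igraph::E(g)
        wmap <- W[cbind(igraph::ends(g, ew, names = FALSE)[, 1],
                        igraph::ends(g, ew, names = FALSE)[, 2])]
        expect_equal(unname(ft[, "W"]),
                     unname(igraph::strength(g, weights = wmap)),
                     tolerance = 1e-10)
        refE <- abs(eigen(A, symmetric = TRUE)$vectors[, 1])
        expect_equal(unname(ft[, "E"]), refE, tolerance = 1e-6)
        expect_equal(unname(ft[, "O"]),
                     unname(igraph::closeness(g, normalized = TRUE)),
                     tolerance = 1e-10)
        refC <- igraph::transitivity(g, type = "local", isolates = "zero")
        expect_equal(unname(ft[, "C"]), unname(refC), tolerance = 1e-10)
        expect_equal(unname(ft[, "B"]),
                     unname(igraph::betweenness(g, normalized = TRUE)),
                     tolerance = 1e-8)
        # hub/authority: the Perron vector of A, which spans the leading
        # eigenspace of A'A (unique even when the graph is bipartite)
        expect_equal(unname(ft[, "A"]), refE, tolerance = 1e-6)
        expect_equal(unname(ft[, "H"]), refE, tolerance = 1e-6)
        expect_identical(unname(ft[, "T"]),
                         as.numeric(igraph::count_triangles(g)))
        expect_equal(unname(ft[, "P"]), pagerankOracle(W), tolerance = 1e-6)
    }
})

test_that("only weighted degree and PageRank respond to weight permutation", {
    inc <- randomIncidence(40, 25, p = 0.3, seed = 77)
    net <- normalizeEdgeWeights(projectToDrugNetwork(inc))
    ft1 <- networkFeatureTable(net)

    net2 <- net
    set.seed(42)
    net2@edges$normWeight <- sample(net2@edges$normWeight)
    ft2 <- networkFeatureTable(net2)

    for (col in c("D", "E", "O", "C", "B", "A", "H", "T"))
        expect_identical(ft1[, col], ft2[, col])
    expect_false(identical(ft1[, "W"], ft2[, "W"]))
    expect_false(identical(ft1[, "P"], ft2[, "P"]))
})

test_that("vertex-transitive graphs score uniformly on every measure", {
    ring <- function(n) {
        A <- matrix(0, n, n)
        A[cbind(seq_len(n), c(2:n, 1))] <- 1
        A + t(A)
    }
    K6 <- matrix(1, 6, 6); diag(K6) <- 0
    for (A in list(K6, ring(7))) {
        net <- netFromAdjacency(A)
        net@edges$normWeight <- 1   # uniform weights keep transitivity
        ft <- networkFeatureTable(net)
        for (col in colnames(ft))
            expect_lt(diff(range(ft[, col])), 1e-8)
    }
})

test_that("feature table assembles columns in the fixed letter order", {
    net <- workedNetwork()
    ft <- networkFeatureTable(net)
    expect_identical(colnames(ft),
                     c("D", "W", "E", "O", "C", "B", "A", "H", "T", "P"))
    expect_identical(rownames(ft), drugNames(net))
    expect_equal(ft[, "D"], degreeCentrality(net))
    expect_equal(ft[, "W"], weightedDegree(net))
    expect_equal(ft[, "T"], as.numeric(triangleCounts(net)),
                 ignore_attr = TRUE)
})

test_that("disconnected and degenerate inputs are handled as documented", {
    # two components: square + edge; closeness uses Wasserman-Faust scaling
    A <- matrix(0, 6, 6)
    A[1, 2] <- A[2, 3] <- A[3, 4] <- A[1, 4] <- A[5, 6] <- 1
    A <- A + t(A)
    net <- netFromAdjacency(A)
    cl <- closenessCentrality(net)
    expect_equal(unname(cl[1]), (3 / 4) * (3 / 5))  # distances 1,2,1 in C4
    expect_equal(unname(cl[5]), (1 / 1) * (1 / 5))

    ev <- eigenvectorCentrality(net)
    expect_false(attr(ev, "connected"))
    expect_true(all(ev[5:6] == 0))  # zeros off the largest component

    single <- new("DrugNetwork", drugIds = "d1",
                  edges = data.frame(from = integer(), to = integer(),
                                     weight = numeric(),
                                     normWeight = numeric()))
    expect_error(degreeCentrality(single), "two nodes")

    P3 <- matrix(0, 3, 3); P3[1, 2] <- P3[2, 3] <- 1; P3 <- P3 + t(P3)
    expect_error(eigenvectorCentrality(netFromAdjacency(P3), maxIter = 1L),
                 "1 iterations")
})
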