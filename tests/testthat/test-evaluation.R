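test_that("ADR eligibility filter thresholds drug counts in order", {
    inc <- workedIncidence()
    expect_identical(filterAdrs(inc, 3), "a1")
    expect_identical(filterAdrs(inc, 0), c("a1", "a2", "a3", "a4"))
    expect_identical(filterAdrs(inc, 5), character(0))
})

test_that("feature assembly follows the ladder letters", {
    net <- workedNetwork()
    ft <- networkFeatureTable(net)
    scores <- matrix(rnorm(40), 4, 10,
                     dimnames = list(drugNames(net), paste0("PC", 1:10)))
    expect_identical(assembleFeatures(scores, ft, character(0)), scores)
    dw <- assembleFeatures(scores, ft, c("D", "W"))
    expect_identical(ncol(dw), 12L)
    expect_identical(colnames(dw)[11:12], c("D", "W"))
    expect_equal(dw[, "W"], weightedDegree(net))
    full <- assembleFeatures(scores, ft, colnames(ft))
    expect_identical(ncol(full), 20L)
    expect_error(assembleFeatures(scores, ft, "Z"), "unknown")

    ladder <- defaultFeatureLadder()
    expect_identical(length(ladder), 11L)
    expect_identical(ladder[[1]], character(0))
    expect_identical(ladder[["baseline+DW"]], c("D", "W"))
    expect_identical(ladder[[11]],
                     c("D", "W", "E", "O", "C", "B", "A", "H", "T", "P"))
})

test_that("AUROC follows the Mann-Whitney tie convention", {
    expect_equal(aurocScore(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1)
    expect_equal(aurocScore(c(0.1, 0.3, 0.8, 0.9), c(1, 1, 0, 0)), 0)
    expect_equal(aurocScore(rep(0.7, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
    expect_true(is.na(aurocScore(1:4, c(1, 1, 1, 1))))
    # rank invariance under monotone transformation
    set.seed(15)
    s <- rnorm(50); y <- rbinom(50, 1, 0.4)
    expect_equal(aurocScore(s, y), aurocScore(exp(s), y))
    expect_equal(aurocScore(s, y), aurocScore(rank(s), y))
})

test_that("AUROC matches brute force and a reference implementation", {
    set.seed(16)
    for (i in 1:25) {
        n <- sample(10:60, 1)
        s <- round(rnorm(n), 1)          # rounding forces ties
        y <- rbinom(n, 1, 0.5)
        if (length(unique(y)) < 2) next
        expect_equal(aurocScore(s, y), aurocBruteForce(s, y))
        ref <- suppressMessages(pROC::auc(pROC::roc(y, s, direction = "<",
                                                    quiet = TRUE)))
        expect_equal(aurocScore(s, y), as.numeric(ref))
    }
})

test_that("cross-validation is reproducible and isolates SMOTE to training", {
    sim <- smallSimulation()
    M <- incidenceMatrix(sim$incidence)
    # pick an eligible ADR rare enough to trip the SMOTE trigger (< 0.4)
    freq <- adrFrequency(sim$incidence)
    adr <- names(freq)[freq >= 10 & freq / (nrow(M) - freq) < 0.4][1]
    X <- transformPCA(fitPCA(oneHotMatrix(sim$features), 5),
                      oneHotMatrix(sim$features))
    y <- M[, adr]
    a <- crossvalAuroc(X, y, "LR", nFolds = 5, seed = 3)
    b <- crossvalAuroc(X, y, "LR", nFolds = 5, seed = 3)
    expect_identical(a, b)
    c <- crossvalAuroc(X, y, "LR", nFolds = 5, seed = 4)
    expect_false(identical(a$folds$auroc, c$folds$auroc))

    # SMOTE fired on training folds while the pool of scored test rows
    # remains exactly the original drugs (sum of test sizes = n)
    expect_gt(sum(a$folds$nSynthetic), 0)
    expect_identical(nrow(a$folds), 5L)
    expect_true(all(a$folds$auroc >= 0 & a$folds$auroc <= 1, na.rm = TRUE))
})

test_that("single-class test folds are excluded from the AUROC mean", {
    set.seed(17)
    X <- matrix(rnorm(60), 30, 2)
    y <- c(rep(1, 3), rep(0, 27))     # 10 folds cannot all hold a positive
    cv <- crossvalAuroc(X, y, "LR", nFolds = 10, seed = 2)
    expect_true(any(cv$folds$singleClassTest))
    expect_true(all(is.na(cv$folds$auroc[cv$folds$singleClassTest])))
    expect_equal(cv$meanAuroc,
                 mean(cv$folds$auroc[!cv$folds$singleClassTest], na.rm = TRUE))
})

test_that("every classifier produces usable scores on separable data", {
    set.seed(18)
    n <- 80
    y <- rep(c(1, 0), c(30, 50))
    X <- cbind(rnorm(n, mean = ifelse(y == 1, 2.5, -2.5), sd = 0.7),
               rnorm(n))
    colnames(X) <- c("signal", "noise")
    for (clf in c("LR", "DT", "XGB", "RF", "SVM", "KNN", "ANN")) {
        cv <- crossvalAuroc(X, y, clf, nFolds = 5, seed = 7)
        expect_false(any(is.na(cv$folds$auroc)), info = clf)
        expect_gt(cv$meanAuroc, 0.9)
        expect_gt(cv$meanAccuracy, 0.8)
    }
})

test_that("a perfect predictor gets a tiny p-value, noise stays uniform", {
    set.seed(19)
    y <- rep(c(1, 0), each = 40)
    X <- cbind(perfect = y + rnorm(80, sd = 0.05), noise = rnorm(80))
    p <- lrFeaturePvalues(X, y)
    expect_lt(p[["perfect"]], 0.01)
    expect_true(attr(p, "converged"))

    # null calibration: p-values of a pure-noise feature are ~ Uniform(0,1)
    hits <- 0; total <- 200
    for (i in 1:total) {
        set.seed(300 + i)
        yy <- rbinom(200, 1, 0.5)
        XX <- cbind(x = rnorm(200))
        pp <- lrFeaturePvalues(XX, yy)
        if (pp[["x"]] < 0.05) hits <- hits + 1
    }
    expect_gte(hits / total, 0.05 - 0.03)
    expect_lte(hits / total, 0.05 + 0.03)
})

test_that("p-values handle duplicated and constant columns", {
    set.seed(20)
    y <- rbinom(100, 1, 0.5)
    x <- rnorm(100)
    X <- cbind(a = x, b = x, const = rep(1, 100))
    p <- lrFeaturePvalues(X, y)
    expect_equal(p[["a"]], p[["b"]])       # twin inherits
    expect_true(is.na(p[["const"]]))

    pw <- lrFeaturePvalues(cbind(a = x, n = rnorm(100)), y, method = "wald")
    expect_true(attr(pw, "converged"))
    expect_true(all(pw >= 0 & pw <= 1))
})

test_that("the evaluation report aggregates consistently", {
    sim <- smallSimulation()
    cfg <- pipelineConfig(minFrequency = 10, nFolds = 5,
                          featureLadder = defaultFeatureLadder()[c(1, 3, 11)],
                          classifiers = "LR", nComponents = 5, seed = 2)
    rep <- evaluateAdrPrediction(sim$incidence, sim$features, cfg)

    eligible <- filterAdrs(sim$incidence, 10)
    expect_identical(nrow(rep@details), length(eligible) * 3L)
    expect_identical(rownames(rep@ladder),
                     c("baseline", "baseline+DW", "baseline+DWEOCBAHTP"))
    expect_true(all(rep@details$meanAuroc >= 0 & rep@details$meanAuroc <= 1))

    # improvement column is the plain difference of recorded AUROCs
    d <- rep@details
    for (a in head(eligible, 3)) {
        base <- d$meanAuroc[d$adr == a & d$featureSet == "baseline"]
        full <- d$meanAuroc[d$adr == a &
                            d$featureSet == "baseline+DWEOCBAHTP"]
        expect_equal(rep@perAdr$improvement[rep@perAdr$adr == a],
                     full - base)
    }
    # per-ADR table is sorted by with-network AUROC
    expect_false(is.unsorted(rev(rep@perAdr$aurocNetwork)))

    # correlation matrix: symmetric with unit diagonal
    fc <- rep@featureCorrelation
    expect_identical(dim(fc), c(10L, 10L))
    expect_equal(unname(diag(fc)), rep(1, 10))
    expect_equal(fc, t(fc))

    # p-value summaries lie in [0, 1]
    expect_true(all(rep@pvalues$meanP >= 0 & rep@pvalues$meanP <= 1,
                    na.rm = TRUE))
})

test_that("pipeline configuration is validated", {
    expect_error(pipelineConfig(classifiers = "GBM"), "unknown classifier")
    expect_error(pipelineConfig(minFrequency = 5, nFolds = 10), ">= nFolds")
    expect_error(pipelineConfig(featureLadder = list(c("D", "Q"))),
                 "unknown letters")
})
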