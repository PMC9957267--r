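#' ADR eligibility filter
#'
#' Keeps the ADRs associated with at least \code{minFrequency} drugs, in
#' their original order. Rare ADRs cannot supply positives to most folds of
#' a 10-fold cross-validation, so they are excluded from evaluation.
#'
#' @param incidence an \linkS4class{AdrIncidence}.
#' @param minFrequency minimum drug count (default 15).
#' @return character vector of eligible ADR identifiers.
#' @export
filterAdrs <- function(incidence, minFrequency = 15L) {
    freq <- adrFrequency(incidence)
    names(freq)[freq >= minFrequency]
}

#' The cumulative network-feature ladder
#'
#' Feature sets evaluated against the baseline: PCA features alone, then
#' cumulatively adding the ten network features in the order D, W, E, O, C,
#' B, A, H, T, P (degree, weighted degree, eigenvector, closeness,
#' clustering, betweenness, authority, hub, triangles, weighted PageRank).
#'
#' @return named list of letter vectors, first entry the empty baseline.
#' @export
defaultFeatureLadder <- function() {
    letters10 <- c("D", "W", "E", "O", "C", "B", "A", "H", "T", "P")
    steps <- lapply(seq_along(letters10), function(i) letters10[seq_len(i)])
    stats::setNames(c(list(character(0)), steps),
                    c("baseline", paste0("baseline+",
                        vapply(steps, paste, "", collapse = ""))))
}

#' Concatenate PCA scores with selected network feature columns
#'
#' @param scores PCA score matrix (drugs x components).
#' @param netFeatures matrix from \code{\link{networkFeatureTable}} with the
#'   same drugs in the same order.
#' @param letters character vector of network feature letters to append, in
#'   ladder order; empty for the baseline.
#' @return numeric feature matrix.
#' @export
assembleFeatures <- function(scores, netFeatures, letters = character(0)) {
    if (!is.null(rownames(scores)) && !is.null(rownames(netFeatures)) &&
        !identical(rownames(scores), rownames(netFeatures)))
        stop("scores and netFeatures must index the same drugs in order")
    unknown <- setdiff(letters, colnames(netFeatures))
    if (length(unknown))
        stop("unknown network feature letter(s): ",
             paste(unknown, collapse = ", "))
    if (!length(letters)) return(scores)
    cbind(scores, netFeatures[, letters, drop = FALSE])
}

#' Pipeline configuration for per-ADR evaluation
#'
#' @param minFrequency minimum drugs per ADR; must be at least
#'   \code{nFolds} so each test fold can hold a positive in most cases.
#' @param nFolds cross-validation folds (default 10).
#' @param featureLadder named list of letter vectors, see
#'   \code{\link{defaultFeatureLadder}}.
#' @param classifiers subset of \code{c("LR", "DT", "XGB", "RF", "SVM",
#'   "KNN", "ANN")}.
#' @param nComponents PCA components for the baseline features.
#' @param smote a \code{\link{smoteConfig}}.
#' @param seed master seed for folds, SMOTE and stochastic classifiers.
#' @param stratified use class-stratified folds instead of a plain shuffle.
#' @return validated list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(minFrequency = 15L, nFolds = 10L,
                           featureLadder = defaultFeatureLadder(),
                           classifiers = "LR", nComponents = 10L,
                           smote = smoteConfig(), seed = 1L,
                           stratified = FALSE) {
    known <- c("LR", "DT", "XGB", "RF", "SVM", "KNN", "ANN")
    if (!all(classifiers %in% known))
        stop("unknown classifier(s): ",
             paste(setdiff(classifiers, known), collapse = ", "))
    if (minFrequency < nFolds)
        stop("minFrequency (", minFrequency, ") must be >= nFolds (",
             nFolds, ")")
    bad <- setdiff(unlist(featureLadder),
                   c("D", "W", "E", "O", "C", "B", "A", "H", "T", "P"))
    if (length(bad))
        stop("featureLadder uses unknown letters: ", paste(bad, collapse = ", "))
    structure(list(minFrequency = as.integer(minFrequency),
                   nFolds = as.integer(nFolds),
                   featureLadder = featureLadder,
                   classifiers = classifiers,
                   nComponents = as.integer(nComponents),
                   smote = smote, seed = as.integer(seed),
                   stratified = stratified),
              class = "PipelineConfig")
}

# ---- classifiers ---------------------------------------------------------
# each returns a numeric score per test row, higher = more likely positive

.fitLR <- function(Xtr, ytr, Xte, seed) {
    df <- data.frame(y = ytr, Xtr, check.names = TRUE)
    fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
    te <- data.frame(Xte, check.names = TRUE)
    names(te) <- names(df)[-1L]
    as.vector(suppressWarnings(stats::predict(fit, te, type = "response")))
}

.fitDT <- function(Xtr, ytr, Xte, seed) {
    df <- data.frame(y = factor(ytr, levels = c(0, 1)), Xtr, check.names = TRUE)
    fit <- rpart::rpart(y ~ ., data = df, method = "class")
    te <- data.frame(Xte, check.names = TRUE)
    names(te) <- names(df)[-1L]
    stats::predict(fit, te, type = "prob")[, "1"]
}

.xgbTrain <- function(Xtr, ytr, depth, eta, seed) {
    dtr <- xgboost::xgb.DMatrix(Xtr, label = ytr, nthread = 1L)
    withSeed(seed, xgboost::xgb.train(
        params = list(max_depth = depth, eta = eta,
                      objective = "binary:logistic", nthread = 1L,
                      seed = seed),
        data = dtr, nrounds = 50L, verbose = 0))
}

.fitXGB <- function(Xtr, ytr, Xte, seed) {
    # small fixed tuning grid on a held-out quarter of the training fold
    grid <- expand.grid(max_depth = c(3L, 6L), eta = c(0.1, 0.3))
    val <- withSeed(seed, sample.int(nrow(Xtr), max(2L, nrow(Xtr) %/% 4L)))
    best <- NULL; bestAuc <- -Inf
    for (i in seq_len(nrow(grid))) {
        fit <- .xgbTrain(Xtr[-val, , drop = FALSE], ytr[-val],
                         grid$max_depth[i], grid$eta[i], seed)
        auc <- aurocScore(stats::predict(fit, xgboost::xgb.DMatrix(
            Xtr[val, , drop = FALSE], nthread = 1L)), ytr[val])
        if (!is.na(auc) && auc > bestAuc) { bestAuc <- auc; best <- grid[i, ] }
    }
    if (is.null(best)) best <- grid[1L, ]
    fit <- .xgbTrain(Xtr, ytr, best$max_depth, best$eta, seed)
    stats::predict(fit, xgboost::xgb.DMatrix(Xte, nthread = 1L))
}

.fitRF <- function(Xtr, ytr, Xte, seed) {
    df <- data.frame(y = factor(ytr, levels = c(0, 1)), Xtr, check.names = TRUE)
    fit <- ranger::ranger(y ~ ., data = df, probability = TRUE,
                          max.depth = 10L, num.trees = 300L, seed = seed,
                          num.threads = 1L)
    te <- data.frame(Xte, check.names = TRUE)
    names(te) <- names(df)[-1L]
    stats::predict(fit, te)$predictions[, "1"]
}

.fitSVM <- function(Xtr, ytr, Xte, seed) {
    fit <- withSeed(seed, e1071::svm(
        x = Xtr, y = factor(ytr, levels = c(0, 1)), probability = TRUE))
    p <- stats::predict(fit, Xte, probability = TRUE)
    attr(p, "probabilities")[, "1"]
}

.fitKNN <- function(Xtr, ytr, Xte, seed) {
    k <- min(5L, nrow(Xtr))
    pred <- withSeed(seed, class::knn(Xtr, Xte,
        factor(ytr, levels = c(0, 1)), k = k, prob = TRUE))
    p <- attr(pred, "prob")        # proportion of votes for the winner
    ifelse(pred == "1", p, 1 - p)
}

.fitANN <- function(Xtr, ytr, Xte, seed) {
    fit <- withSeed(seed, nnet::nnet(
        x = Xtr, y = ytr, size = 32L, decay = 1e-4, maxit = 200L,
        entropy = TRUE, trace = FALSE, MaxNWts = 5000L))
    as.vector(stats::predict(fit, Xte))
}

.classifierFuns <- list(LR = .fitLR, DT = .fitDT, XGB = .fitXGB,
                        RF = .fitRF, SVM = .fitSVM, KNN = .fitKNN,
                        ANN = .fitANN)

.makeFolds <- function(y, nFolds, seed, stratified) {
    n <- length(y)
    withSeed(seed, {
        if (stratified) {
            fold <- integer(n)
            for (cls in unique(y)) {
                idx <- which(y == cls)
                fold[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
            }
            fold
        } else sample(rep_len(seq_len(nFolds), n))
    })
}

#' SMOTE-balanced cross-validated AUROC for one ADR
#'
#' Folds come from a seeded shuffle split. Within each fold, if the
#' training positives/negatives ratio falls below the SMOTE trigger, the
#' training portion (only) is oversampled; the test fold is never touched.
#' AUROC is the Mann-Whitney rank statistic of the predicted scores on the
#' untouched test fold (folds whose test part has a single class contribute
#' no AUROC and are excluded from the mean, flagged in the fold table);
#' accuracy thresholds scores at 0.5.
#'
#' @param X feature matrix (drugs x features).
#' @param y binary labels (1 = drug shows the ADR).
#' @param classifier one of \code{"LR"}, \code{"DT"}, \code{"XGB"},
#'   \code{"RF"}, \code{"SVM"}, \code{"KNN"}, \code{"ANN"}.
#' @param nFolds number of folds.
#' @param smote a \code{\link{smoteConfig}}.
#' @param seed fold/SMOTE/classifier seed.
#' @param stratified class-stratified fold assignment.
#' @return list with \code{meanAuroc}, \code{meanAccuracy} and a per-fold
#'   data.frame \code{folds} (fold, auroc, accuracy, nSynthetic,
#'   singleClassTest, skipped, error).
#' @export
crossvalAuroc <- function(X, y, classifier = "LR", nFolds = 10L,
                          smote = smoteConfig(), seed = 1L,
                          stratified = FALSE) {
    X <- as.matrix(X)
    y <- as.integer(y == 1)
    stopifnot(nrow(X) == length(y), classifier %in% names(.classifierFuns))
    if (length(unique(y)) < 2L)
        stop("both classes must be present overall")
    fun <- .classifierFuns[[classifier]]
    fold <- .makeFolds(y, nFolds, seed, stratified)
    rows <- vector("list", nFolds)
    for (f in seq_len(nFolds)) {
        te <- fold == f
        Xtr <- X[!te, , drop = FALSE]; ytr <- y[!te]
        Xte <- X[te, , drop = FALSE]; yte <- y[te]
        nSynth <- 0L
        res <- tryCatch({
            nPos <- sum(ytr == 1L); nNeg <- sum(ytr == 0L)
            if (nNeg > 0L && nPos / nNeg < smote$triggerRatio) {
                cfg <- smote
                cfg$seed <- smote$seed %||% (seed + f)
                sm <- smoteOversample(Xtr, ytr, cfg)
                Xtr <- sm$X; ytr <- sm$y; nSynth <- sm$nCreated
            }
            scores <- fun(Xtr, ytr, Xte, seed = seed + f)
            list(auroc = aurocScore(scores, yte),
                 accuracy = accuracyScore(scores, yte), error = NA_character_)
        }, error = function(e)
            list(auroc = NA_real_, accuracy = NA_real_,
                 error = conditionMessage(e)))
        rows[[f]] <- data.frame(
            fold = f, auroc = res$auroc, accuracy = res$accuracy,
            nSynthetic = nSynth,
            singleClassTest = length(unique(yte)) < 2L,
            skipped = !is.na(res$error) || is.na(res$auroc),
            error = res$error, stringsAsFactors = FALSE)
    }
    folds <- do.call(rbind, rows)
    list(meanAuroc = mean(folds$auroc, na.rm = TRUE),
         meanAccuracy = mean(folds$accuracy, na.rm = TRUE),
         folds = folds)
}

#' Logistic-regression Wald p-values per feature
#'
#' Fits a logistic regression of the ADR label on the feature columns
#' (after one SMOTE pass on the full set when the class ratio falls below
#' the trigger) and returns the two-sided Wald p-value of each feature
#' from the asymptotic covariance (inverse information).
#'
#' The default fit is Firth's bias-reduced logistic regression. On a
#' near-complete drug network several centrality columns are nearly
#' constant and the classes frequently become linearly separable, under
#' which the maximum-likelihood estimate diverges and its Wald test
#' collapses; the Jeffreys-prior penalty keeps the estimates finite and the
#' tests usable while leaving well-behaved fits essentially unchanged.
#' \code{method = "wald"} gives the classic unpenalised fit, flagging
#' (quasi-)separation. Columns are standardised before fitting (the Wald
#' p-value of a coefficient is invariant to rescaling its column) and
#' columns beyond the numerical rank of the design (e.g. hub vs authority,
#' which coincide on an undirected network) are dropped from the fit and
#' inherit the p-value of a retained column they are numerically identical
#' to (absolute correlation > 1 - 1e-6); constant columns get \code{NA}.
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param smote a \code{\link{smoteConfig}}; oversampling applied once on
#'   the full set when triggered.
#' @param seed SMOTE seed.
#' @param method \code{"firth"} (default) or \code{"wald"} (unpenalised).
#' @return named numeric vector of p-values, one per feature column, with
#'   \code{attr(, "converged")}; non-converged (or, for
#'   \code{method = "wald"}, separated) fits are flagged so callers can
#'   exclude them from aggregates.
#' @export
lrFeaturePvalues <- function(X, y, smote = smoteConfig(), seed = 1L,
                             method = c("firth", "wald")) {
    method <- match.arg(method)
    X <- as.matrix(X)
    y <- as.integer(y == 1)
    nPos <- sum(y == 1L); nNeg <- sum(y == 0L)
    if (nNeg > 0L && nPos > 1L && nPos / nNeg < smote$triggerRatio) {
        cfg <- smote
        cfg$seed <- smote$seed %||% seed
        sm <- smoteOversample(X, y, cfg)
        X <- sm$X; y <- sm$y
    }

    p <- rep(NA_real_, ncol(X))
    names(p) <- colnames(X)
    sds <- apply(X, 2L, stats::sd)
    keep <- which(sds > 0)
    if (!length(keep)) {
        attr(p, "converged") <- FALSE
        return(p)
    }
    Xs <- scale(X[, keep, drop = FALSE])
    q <- qr(Xs)
    ret <- keep[q$pivot[seq_len(q$rank)]]
    dropped <- setdiff(keep, ret)
    Xf <- scale(X[, ret, drop = FALSE])

    fit <- if (method == "firth") .firthFit(Xf, y)
           else .waldFit(Xf, y)
    p[ret] <- fit$p
    if (length(dropped)) {
        cc <- abs(suppressWarnings(
            stats::cor(X[, dropped, drop = FALSE], X[, ret, drop = FALSE])))
        for (i in seq_along(dropped)) {
            j <- which.max(cc[i, ])
            if (isTRUE(cc[i, j] > 1 - 1e-6)) p[dropped[i]] <- p[ret[j]]
        }
    }
    attr(p, "converged") <- fit$converged
    p
}

# Firth bias-reduced logistic regression: Fisher scoring on the
# Jeffreys-penalised score U*(b) = X'(y - mu + h (1/2 - mu)), with
# step-halving on the penalised log-likelihood
.firthFit <- function(X, y, maxIter = 1000L, tol = 1e-6) {
    Xd <- cbind(1, X)
    beta <- numeric(ncol(Xd))
    penLik <- function(b) {
        eta <- as.vector(Xd %*% b); mu <- stats::plogis(eta)
        I <- crossprod(Xd, Xd * (mu * (1 - mu)))
        sum(y * eta - log1p(exp(eta))) +
            0.5 * as.numeric(determinant(I)$modulus)
    }
    conv <- FALSE
    Iinv <- NULL
    for (it in seq_len(maxIter)) {
        eta <- as.vector(Xd %*% beta); mu <- stats::plogis(eta)
        w <- mu * (1 - mu); XW <- Xd * w
        I <- crossprod(Xd, XW)
        Iinv <- tryCatch(solve(I), error = function(e) NULL)
        if (is.null(Iinv)) break
        h <- rowSums((Xd %*% Iinv) * XW)
        U <- crossprod(Xd, y - mu + h * (0.5 - mu))
        delta <- as.vector(Iinv %*% U)
        f0 <- penLik(beta); step <- 1
        while (step > 1 / 64 && penLik(beta + step * delta) < f0)
            step <- step / 2
        beta <- beta + step * delta
        if (max(abs(step * delta)) < tol) { conv <- TRUE; break }
    }
    if (is.null(Iinv) || !conv)
        return(list(p = rep(NA_real_, ncol(X)), converged = FALSE))
    se <- sqrt(diag(Iinv))
    list(p = (2 * stats::pnorm(-abs(beta / se)))[-1L], converged = TRUE)
}

.waldFit <- function(X, y) {
    sep <- FALSE
    df <- data.frame(y = y, X, check.names = TRUE)
    fit <- withCallingHandlers(
        stats::glm(y ~ ., data = df, family = stats::binomial()),
        warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1",
                      conditionMessage(w)))
                sep <<- TRUE
            invokeRestart("muffleWarning")
        })
    coefs <- summary(fit)$coefficients
    p <- rep(NA_real_, ncol(X))
    hit <- match(make.names(colnames(X)), rownames(coefs))
    p[!is.na(hit)] <- coefs[hit[!is.na(hit)], "Pr(>|z|)"]
    list(p = p, converged = fit$converged && !sep && !anyNA(p))
}

#' Run the full per-ADR evaluation pipeline
#'
#' Reproduces the experiment design end to end: PCA is fitted once on the
#' concatenated one-hot drug features (all drugs); the drug-to-drug network
#' is projected from the full incidence matrix, its weights min-max
#' normalised, and the ten centrality features extracted; every ADR with at
#' least \code{minFrequency} associated drugs is then evaluated with each
#' classifier on each feature set of the ladder under SMOTE-balanced
#' cross-validation; finally logistic-regression Wald p-values of the ten
#' network features (on the full feature set) are aggregated per feature.
#'
#' Note the network is deliberately built from the full incidence, target
#' ADR included, as the experiment design prescribes; set
#' \code{holdoutAdrEdges = TRUE} for the leakage-free variant that rebuilds
#' the network without the target ADR's associations for each ADR.
#'
#' @param incidence an \linkS4class{AdrIncidence}.
#' @param features a \linkS4class{DrugFeatureSet} (or a plain drugs x
#'   features binary matrix) for the baseline representation.
#' @param config a \code{\link{pipelineConfig}}.
#' @param holdoutAdrEdges rebuild the network excluding the target ADR.
#' @return an \linkS4class{AdrEvaluationReport}.
#' @export
evaluateAdrPrediction <- function(incidence, features,
                                  config = pipelineConfig(),
                                  holdoutAdrEdges = FALSE) {
    stopifnot(is(incidence, "AdrIncidence"),
              inherits(config, "PipelineConfig"))
    X1 <- if (is(features, "DrugFeatureSet")) oneHotMatrix(features)
          else as.matrix(features)
    if (!identical(rownames(X1), drugNames(incidence)))
        stop("features and incidence must index the same drugs in order")

    scores <- transformPCA(fitPCA(X1, config$nComponents), X1)
    rownames(scores) <- rownames(X1)

    net <- normalizeEdgeWeights(projectToDrugNetwork(incidence))
    netTab <- networkFeatureTable(net)

    M <- incidenceMatrix(incidence)
    eligible <- filterAdrs(incidence, config$minFrequency)
    if (!length(eligible)) stop("no ADR reaches minFrequency = ",
                                config$minFrequency)

    ladder <- config$featureLadder
    rows <- list()
    pmat <- matrix(NA_real_, length(eligible), ncol(netTab),
                   dimnames = list(eligible, colnames(netTab)))
    converged <- logical(length(eligible))
    allLetters <- colnames(netTab)

    for (ai in seq_along(eligible)) {
        adr <- eligible[ai]
        y <- M[, adr]
        nt <- netTab
        if (holdoutAdrEdges) {
            inc2 <- AdrIncidence(M[, colnames(M) != adr, drop = FALSE])
            nt <- networkFeatureTable(
                normalizeEdgeWeights(projectToDrugNetwork(inc2)))
        }
        adrSeed <- config$seed + ai
        for (li in seq_along(ladder)) {
            Xf <- assembleFeatures(scores, nt, ladder[[li]])
            for (clf in config$classifiers) {
                cv <- crossvalAuroc(Xf, y, clf, config$nFolds, config$smote,
                                    seed = adrSeed,
                                    stratified = config$stratified)
                rows[[length(rows) + 1L]] <- data.frame(
                    adr = adr, classifier = clf,
                    featureSet = names(ladder)[li],
                    meanAuroc = cv$meanAuroc, meanAccuracy = cv$meanAccuracy,
                    nFoldsUsed = sum(!cv$folds$skipped),
                    stringsAsFactors = FALSE)
            }
        }
        pv <- lrFeaturePvalues(assembleFeatures(scores, nt, allLetters), y,
                               config$smote, seed = adrSeed)
        converged[ai] <- isTRUE(attr(pv, "converged"))
        if (converged[ai]) pmat[ai, ] <- pv[allLetters]
    }

    details <- do.call(rbind, rows)
    aggregateReport(details, pmat[converged, , drop = FALSE], netTab,
                    config)
}

#' Aggregate per-ADR results into an evaluation report
#'
#' Builds the classifier-by-ladder mean AUROC matrix, the per-ADR
#' improvement table (full feature set vs baseline, sorted by with-network
#' AUROC), the per-feature mean/sd of the logistic-regression p-values, and
#' the Pearson correlation matrix of the ten network feature columns.
#'
#' @param details data.frame with columns adr, classifier, featureSet,
#'   meanAuroc, meanAccuracy.
#' @param pvalueMatrix per-ADR p-values (converged fits only).
#' @param netFeatures the network feature table used.
#' @param config the pipeline configuration (stored in the report).
#' @return an \linkS4class{AdrEvaluationReport}.
#' @export
aggregateReport <- function(details, pvalueMatrix, netFeatures,
                            config = pipelineConfig()) {
    sets <- unique(details$featureSet)
    clfs <- unique(details$classifier)
    ladder <- sapply(clfs, function(cl) sapply(sets, function(fs)
        mean(details$meanAuroc[details$classifier == cl &
                               details$featureSet == fs], na.rm = TRUE)))
    ladder <- as.data.frame(matrix(ladder, nrow = length(sets),
                                   dimnames = list(sets, clfs)))

    base <- sets[1L]; full <- sets[length(sets)]
    cl1 <- clfs[1L]
    d1 <- details[details$classifier == cl1, ]
    adrs <- unique(d1$adr)
    g <- function(fs, col) {
        m <- d1[d1$featureSet == fs, ]
        m[[col]][match(adrs, m$adr)]
    }
    perAdr <- data.frame(
        adr = adrs,
        aurocBaseline = g(base, "meanAuroc"),
        aurocNetwork = g(full, "meanAuroc"),
        improvement = g(full, "meanAuroc") - g(base, "meanAuroc"),
        accuracyNetwork = g(full, "meanAccuracy"),
        stringsAsFactors = FALSE)
    perAdr <- perAdr[order(-perAdr$aurocNetwork), ]
    rownames(perAdr) <- NULL

    pvals <- data.frame(
        feature = colnames(pvalueMatrix),
        meanP = apply(pvalueMatrix, 2L, mean),
        sdP = apply(pvalueMatrix, 2L, stats::sd),
        nAdrs = nrow(pvalueMatrix),
        stringsAsFactors = FALSE)
    rownames(pvals) <- NULL

    fc <- suppressWarnings(stats::cor(netFeatures))
    diag(fc) <- 1

    new("AdrEvaluationReport", details = details, ladder = ladder,
        perAdr = perAdr, pvalues = pvals, pvalueMatrix = pvalueMatrix,
        featureCorrelation = fc, config = unclass(config))
}
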