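#' Fit a principal component model on one-hot drug features
#'
#' Mean-centres the matrix and takes the singular value decomposition;
#' components are the right singular vectors ordered by decreasing
#' explained variance. The full singular spectrum is retained so
#' \code{\link{varianceCurve}} can report cumulative explained variance for
#' any component count. Ten components are the conventional choice for the
#' downstream classifiers (roughly half the variance of a one-hot
#' pharmacological feature set at full scale).
#'
#' @param X numeric matrix, drugs in rows.
#' @param nComponents number of components to retain (default 10).
#' @return a \linkS4class{PCAModel}.
#' @export
fitPCA <- function(X, nComponents = 10L) {
    X <- as.matrix(X)
    if (nrow(X) < 2L) stop("PCA needs at least two rows")
    if (nComponents > min(dim(X)))
        stop("nComponents (", nComponents, ") exceeds min(rows, cols) = ",
             min(dim(X)))
    ctr <- colMeans(X)
    Xc <- sweep(X, 2L, ctr)
    sv <- svd(Xc)
    total <- sum(sv$d^2)
    ratio <- if (total > 0) sv$d^2 / total else rep(0, length(sv$d))
    k <- as.integer(nComponents)
    new("PCAModel", center = ctr,
        rotation = sv$v[, seq_len(k), drop = FALSE],
        varianceRatio = ratio[seq_len(k)],
        fullVarianceRatio = ratio)
}

#' Project drugs onto a fitted principal component model
#'
#' @param model a \linkS4class{PCAModel}.
#' @param X matrix with the same columns the model was fitted on.
#' @return score matrix (drugs x components), columns \code{PC1..PCk}.
#' @export
transformPCA <- function(model, X) {
    stopifnot(is(model, "PCAModel"))
    X <- as.matrix(X)
    if (ncol(X) != length(model@center))
        stop("X has ", ncol(X), " columns but the model was fitted on ",
             length(model@center))
    scores <- sweep(X, 2L, model@center) %*% model@rotation
    colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
    scores
}

#' Cumulative explained-variance curve
#'
#' @param model a \linkS4class{PCAModel}.
#' @return numeric vector: cumulative explained-variance ratio at each
#'   component count over the full spectrum.
#' @export
varianceCurve <- function(model) {
    stopifnot(is(model, "PCAModel"))
    cumsum(model@fullVarianceRatio)
}

#' @rdname varianceCurve
#' @param threshold target cumulative explained-variance ratio.
#' @return \code{componentsForVariance}: smallest component count whose
#'   cumulative ratio reaches \code{threshold}.
#' @export
componentsForVariance <- function(model, threshold = 0.5) {
    curve <- varianceCurve(model)
    idx <- which(curve >= threshold)
    if (!length(idx))
        stop("no component count reaches a cumulative ratio of ", threshold)
    idx[1L]
}

#' SMOTE configuration
#'
#' @param kNeighbors number of nearest minority neighbours considered when
#'   interpolating (k = 5 conventionally); capped at the number of other
#'   minority points when the class is smaller than k + 1.
#' @param samplingRatio target minority/majority ratio after oversampling;
#'   the number of synthetic points is
#'   \code{max(0, floor(samplingRatio * n_majority) - n_minority)}.
#' @param triggerRatio oversampling is applied only when the observed
#'   positive/negative ratio falls below this value.
#' @param seed optional integer making the oversampling deterministic.
#' @return a validated list of class \code{"SmoteConfig"}.
#' @export
smoteConfig <- function(kNeighbors = 5L, samplingRatio = 0.43,
                        triggerRatio = 0.4, seed = NULL) {
    stopifnot(kNeighbors >= 1L, samplingRatio > 0, triggerRatio > 0)
    structure(list(kNeighbors = as.integer(kNeighbors),
                   samplingRatio = samplingRatio,
                   triggerRatio = triggerRatio, seed = seed),
              class = "SmoteConfig")
}

#' Synthetic minority oversampling (SMOTE)
#'
#' Brings the minority (positive) class up to
#' \code{floor(samplingRatio * n_majority)} samples by interpolation: each
#' synthetic point is \code{x + u * (x_nbr - x)} with \code{u} uniform on
#' [0, 1], \code{x} a randomly chosen minority point and \code{x_nbr} one of
#' its k nearest minority neighbours by Euclidean distance (ties broken by
#' lowest row index). Original rows are never altered or removed; synthetic
#' rows are appended and tagged so they can be kept out of test folds.
#'
#' @param X numeric feature matrix.
#' @param y binary labels, 1 = minority/positive.
#' @param config a \code{\link{smoteConfig}}.
#' @return list with elements \code{X} (original rows then synthetic rows),
#'   \code{y}, \code{synthetic} (logical tag per row) and \code{nCreated}.
#' @examples
#' X <- matrix(rnorm(24), ncol = 2)
#' y <- c(1, 1, rep(0, 10))
#' smoteOversample(X, y, smoteConfig(samplingRatio = 0.5, seed = 1))$nCreated
#' @export
smoteOversample <- function(X, y, config = smoteConfig()) {
    stopifnot(inherits(config, "SmoteConfig"))
    X <- as.matrix(X)
    y <- as.integer(y == 1)
    stopifnot(nrow(X) == length(y))
    minIdx <- which(y == 1L)
    nMin <- length(minIdx); nMaj <- sum(y == 0L)
    target <- floor(config$samplingRatio * nMaj)
    nCreated <- max(0L, as.integer(target) - nMin)
    if (nCreated == 0L)
        return(list(X = X, y = y, synthetic = rep(FALSE, nrow(X)),
                    nCreated = 0L))
    if (nMin < 2L)
        stop("SMOTE needs at least two minority samples (got ", nMin, ")")
    k <- min(config$kNeighbors, nMin - 1L)

    Xmin <- X[minIdx, , drop = FALSE]
    D <- as.matrix(stats::dist(Xmin))
    diag(D) <- Inf
    # k nearest minority neighbours per minority point, ties to lowest index
    nbrs <- apply(D, 1L, function(d) order(d)[seq_len(k)], simplify = FALSE)

    gen <- function() {
        base <- sample.int(nMin, nCreated, replace = TRUE)
        pick <- vapply(base, function(b) nbrs[[b]][sample.int(k, 1L)],
                       integer(1))
        u <- stats::runif(nCreated)
        Xmin[base, , drop = FALSE] +
            u * (Xmin[pick, , drop = FALSE] - Xmin[base, , drop = FALSE])
    }
    synth <- if (is.null(config$seed)) gen() else withSeed(config$seed, gen())
    rownames(synth) <- NULL
    list(X = rbind(X, synth), y = c(y, rep(1L, nCreated)),
         synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, nCreated)),
         nCreated = nCreated)
}
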