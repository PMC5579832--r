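#' @include accessors.R
NULL

## force the largest-magnitude element of a vector positive (stable signs
## for scores/loadings across platforms)
.fixSign <- function(v) {
    j <- which.max(abs(v))
    if (v[j] < 0) -v else v
}

#' Principal component analysis
#'
#' Mean-centered PCA by eigen-decomposition of the column covariance matrix.
#' Used for exploratory inspection of sensor data (clusters, outliers,
#' non-typical measurement positions) before supervised modeling. The sign of
#' each loading vector is fixed so that its largest-magnitude element is
#' positive.
#'
#' @param X numeric samples-by-variables matrix, or a
#'   [SpectraSet]/[SensorTable].
#' @param nComponents number of components, at most `min(nrow - 1, ncol)`.
#' @return a [PCAModel-class] with orthonormal loadings, scores
#'   (`centered X %*% loadings`), per-component explained-variance fractions
#'   and the training column means.
#' @examples
#' m <- fitPCA(matrix(rnorm(60), 10), 3)
#' explainedVariance(m)
#' @export
fitPCA <- function(X, nComponents) {
    if (is(X, "MeasurementSet"))
        X <- intensityMatrix(X)
    X <- .checkMatrix(X)
    kmax <- min(nrow(X) - 1L, ncol(X))
    if (nComponents < 1L || nComponents > kmax)
        stop(sprintf("'nComponents' must lie in [1, %d] for a %d x %d matrix",
            kmax, nrow(X), ncol(X)))
    mc <- meanCenter(X)
    Xc <- mc$centered
    S <- crossprod(Xc) / (nrow(Xc) - 1L)
    e <- eigen(S, symmetric = TRUE)
    ev <- pmax(e$values, 0)
    L <- e$vectors[, seq_len(nComponents), drop = FALSE]
    for (j in seq_len(ncol(L)))
        L[, j] <- .fixSign(L[, j])
    rownames(L) <- colnames(X)
    colnames(L) <- paste0("PC", seq_len(nComponents))
    scores <- Xc %*% L
    new("PCAModel", loadings = L, scores = scores,
        explainedVariance = ev[seq_len(nComponents)] / sum(ev),
        columnMeans = mc$means)
}

#' Fit a PLS-DA discrimination model
#'
#' PLS1 regression of the 0/1 diagnosis code on mean-centered predictors,
#' fitted by NIPALS with deflation of X only (sufficient for a single
#' response). No autoscaling is applied - variables are mean-centered only.
#' The continuous prediction for a new observation x is
#' `(x - xMeans) %*% b + yMean`; [predictClass()] thresholds it.
#'
#' @param X numeric samples-by-variables matrix, or a
#'   [SpectraSet]/[SensorTable] (its class labels are used when `y` is
#'   missing).
#' @param y numeric 0/1 response (0 = normal, 1 = tumor); both classes must
#'   be present.
#' @param nLV number of latent variables (default 2).
#' @param threshold decision threshold stored with the model (default 0.5).
#' @return a [PLSDAModel-class].
#' @examples
#' X <- rbind(matrix(rnorm(20), 5), matrix(rnorm(20, 3), 5))
#' m <- fitPLSDA(X, rep(c(0, 1), each = 5), nLV = 2)
#' predictClass(predictResponse(m, X), threshold(m))
#' @export
fitPLSDA <- function(X, y = NULL, nLV = 2L, threshold = 0.5) {
    if (is(X, "MeasurementSet")) {
        if (is.null(y))
            y <- classLabels(X)
        X <- intensityMatrix(X)
    }
    X <- .checkMatrix(X)
    y <- .checkBinary(y)
    if (length(y) != nrow(X))
        stop("'y' length must equal the number of rows of 'X'")
    if (length(unique(y)) < 2L)
        stop("both classes must be present in 'y'")
    nLV <- as.integer(nLV)
    if (nLV < 1L)
        stop("'nLV' must be at least 1")
    mc <- meanCenter(X)
    Xc <- mc$centered
    if (all(abs(Xc) < 1e-12))
        stop("'X' has zero variance; nothing to model")
    yc <- y - mean(y)
    p <- ncol(X)
    W <- matrix(0, p, nLV)
    P <- matrix(0, p, nLV)
    Tm <- matrix(0, nrow(X), nLV)
    q <- numeric(nLV)
    Xd <- Xc
    for (a in seq_len(nLV)) {
        w <- crossprod(Xd, yc)[, 1L]
        nw <- sqrt(sum(w^2))
        if (nw < 1e-12)
            stop(sprintf(
                "cannot extract latent variable %d: no covariance left", a))
        w <- .fixSign(w / nw)
        t <- Xd %*% w
        tt <- sum(t^2)
        if (tt < 1e-12)
            stop(sprintf("cannot extract latent variable %d: degenerate %s",
                a, "score vector"))
        pv <- crossprod(Xd, t)[, 1L] / tt
        q[a] <- sum(yc * t) / tt
        Xd <- Xd - tcrossprod(t, pv)
        W[, a] <- w
        P[, a] <- pv
        Tm[, a] <- t
    }
    b <- as.vector(W %*% solve(crossprod(P, W), q))
    names(b) <- colnames(X)
    dimnames(W) <- dimnames(P) <- list(colnames(X),
        paste0("LV", seq_len(nLV)))
    colnames(Tm) <- paste0("LV", seq_len(nLV))
    fittedY <- as.vector(Xc %*% b) + mean(y)
    new("PLSDAModel", nLV = nLV, xWeights = W, xLoadings = P, scores = Tm,
        coefficients = b, xMeans = mc$means, yMean = mean(y),
        threshold = as.numeric(threshold), fitted = fittedY)
}

#' Predict the continuous PLS-DA response
#'
#' Applies the regression vector to new observations after subtracting the
#' training column means. Responses are not clipped to `[0, 1]`.
#'
#' @param model a [PLSDAModel-class].
#' @param XNew numeric matrix (or [SpectraSet]/[SensorTable]) whose column
#'   count matches the training data.
#' @return numeric vector of predicted responses.
#' @export
predictResponse <- function(model, XNew) {
    stopifnot(is(model, "PLSDAModel"))
    if (is(XNew, "MeasurementSet"))
        XNew <- intensityMatrix(XNew)
    if (is.null(dim(XNew)))
        XNew <- matrix(XNew, nrow = 1L)
    if (ncol(XNew) != length(model@coefficients))
        stop(sprintf("'XNew' has %d columns but the model was trained on %d",
            ncol(XNew), length(model@coefficients)))
    as.vector(sweep(XNew, 2L, model@xMeans, `-`) %*% model@coefficients) +
        model@yMean
}

#' Threshold continuous responses into 0/1 classes
#'
#' Class 1 (tumor) iff the response is at least the threshold; ties go to the
#' tumor class, the conservative choice when false negatives are the costly
#' error. A threshold of 0.47 instead of the standard 0.5 recovers full
#' separation when tumor predictions scatter slightly below 0.5.
#'
#' @param yPred numeric vector of continuous responses.
#' @param threshold decision threshold (default 0.5).
#' @return numeric 0/1 vector.
#' @examples
#' predictClass(c(0.46, 0.48), threshold = 0.47)  # 0 1
#' @export
predictClass <- function(yPred, threshold = 0.5) {
    as.numeric(as.numeric(yPred) >= threshold)
}
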