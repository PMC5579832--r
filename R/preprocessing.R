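#' @include accessors.R
NULL

#' Column mean centering
#'
#' Subtracts the column means from a samples-by-variables matrix. Centering
#' precedes every multivariate model in this package; for few-channel sensor
#' data it is the only preprocessing applied.
#'
#' @param X numeric matrix (or [SpectraSet]/[SensorTable], whose data matrix
#'   is used) with at least one row.
#' @param means optional externally supplied column means (e.g. training-set
#'   means applied to new data).
#' @return a list with elements `centered` (matrix of the same shape) and
#'   `means` (the column means that were subtracted).
#' @examples
#' meanCenter(cbind(c(1, 2, 3)))$centered
#' @export
meanCenter <- function(X, means = NULL) {
    if (is(X, "MeasurementSet"))
        X <- intensityMatrix(X)
    X <- .checkMatrix(X)
    if (is.null(means))
        means <- colMeans(X)
    if (length(means) != ncol(X))
        stop("'means' length must equal the number of columns")
    list(centered = sweep(X, 2L, means, `-`), means = means)
}

#' Savitzky-Golay second derivative
#'
#' Per-row second derivative by local polynomial least-squares smoothing,
#' with a second-order polynomial and a 25-point window by default. The
#' derivative is taken with respect to the column index (per-point spacing),
#' the common chemometrics convention; supply `spacing` (nm per point) to
#' rescale to physical units. Edge points are computed from one-sided
#' polynomial fits; interior points carry the usual symmetric-window
#' convolution weights.
#'
#' @param X numeric matrix (rows = spectra) or a [SpectraSet], in which case
#'   a [SpectraSet] is returned.
#' @param window odd window width in points (default 25), at most the number
#'   of columns.
#' @param polyorder polynomial order (default 2), less than `window`.
#' @param spacing abscissa step used to scale the derivative (default 1 =
#'   per-index).
#' @return matrix (or [SpectraSet]) of the same shape.
#' @examples
#' x <- matrix((1:60)^2, 1)        # quadratic row
#' d <- savgolSecondDerivative(x, window = 11)
#' range(d[, 20:40])               # ~2 everywhere in the interior
#' @importFrom signal sgolayfilt
#' @export
savgolSecondDerivative <- function(X, window = 25L, polyorder = 2L,
                                   spacing = 1) {
    obj <- NULL
    if (is(X, "SpectraSet")) {
        obj <- X
        X <- intensityMatrix(X)
    }
    X <- .checkMatrix(X)
    window <- as.integer(window)
    if (window %% 2L == 0L)
        stop("'window' must be odd")
    if (window <= polyorder)
        stop("'window' must exceed 'polyorder'")
    if (window > ncol(X))
        stop(sprintf("'window' (%d) exceeds the number of columns (%d)",
            window, ncol(X)))
    D <- t(apply(X, 1L, sgolayfilt, p = polyorder, n = window, m = 2L,
        ts = spacing))
    dimnames(D) <- dimnames(X)
    if (!is.null(obj)) {
        obj@values <- D
        obj
    } else D
}

#' Standard normal variate (SNV) transform
#'
#' Standardizes each row to mean 0 and standard deviation 1, the classical
#' scatter correction. Provided because for intensity-based tissue
#' discrimination it removes the very offset/contrast signal that separates
#' the classes - applying it is expected to destroy the discrimination, and
#' tests exercise exactly that behaviour.
#'
#' @param X numeric matrix (rows = spectra) or a [SpectraSet].
#' @return matrix (or [SpectraSet]) of the same shape; each row has mean 0
#'   and unit standard deviation. Idempotent.
#' @export
snv <- function(X) {
    obj <- NULL
    if (is(X, "SpectraSet")) {
        obj <- X
        X <- intensityMatrix(X)
    }
    X <- .checkMatrix(X)
    m <- rowMeans(X)
    s <- apply(X, 1L, stats::sd)
    if (any(s == 0)) {
        bad <- which(s == 0)[1L]
        lab <- if (!is.null(rownames(X))) rownames(X)[bad] else bad
        stop(sprintf("row '%s' is constant; SNV undefined", lab))
    }
    out <- (X - m) / s
    dimnames(out) <- dimnames(X)
    if (!is.null(obj)) {
        obj@values <- out
        obj
    } else out
}
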