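#' @include metrics.R
NULL

.resolveXY <- function(X, y) {
    if (is(X, "MeasurementSet")) {
        if (is.null(y))
            y <- classLabels(X)
        X <- intensityMatrix(X)
    }
    list(X = .checkMatrix(X), y = .checkBinary(y))
}

#' Build cross-validation segments from measurement identifiers
#'
#' Repeated measurements of the same sample position produce near-identical
#' data; holding them out one at a time leaks information between folds.
#' `positionSegments()` groups rows by sample+position (`"N144_Cn"`);
#' `sampleSegments()` groups by whole sample (`"T151"`), the scheme used when
#' measurement positions are arbitrary.
#'
#' @param ids character vector of measurement identifiers (or a
#'   [SpectraSet]/[SensorTable]).
#' @return named list of integer row-index vectors partitioning
#'   `seq_along(ids)`.
#' @examples
#' positionSegments(c("N144_Cn_1", "N144_Cn_2", "T144_B2_1"))
#' @export
positionSegments <- function(ids) {
    if (is(ids, "MeasurementSet"))
        ids <- measurementIDs(ids)
    unname2 <- split(seq_along(ids), factor(positionKey(ids),
        levels = unique(positionKey(ids))))
    unname2
}

#' @rdname positionSegments
#' @export
sampleSegments <- function(ids) {
    if (is(ids, "MeasurementSet"))
        ids <- measurementIDs(ids)
    split(seq_along(ids), factor(sampleKey(ids),
        levels = unique(sampleKey(ids))))
}

.checkSegments <- function(segments, n) {
    idx <- unlist(segments, use.names = FALSE)
    if (any(lengths(segments) == 0L))
        stop("every segment must be non-empty")
    if (length(idx) != n || !setequal(idx, seq_len(n)) ||
        anyDuplicated(idx))
        stop("segments must partition all rows exactly once")
    segments
}

#' Segmented (grouped) cross-validation
#'
#' Holds out each segment in turn, refits the PLS-DA model on the remaining
#' rows (mean centering recomputed per fold), predicts the held-out rows, and
#' pools all out-of-fold predictions into a single [PredictionSet] from which
#' one report is assembled. With singleton segments this is exactly
#' leave-one-out CV.
#'
#' @param X numeric matrix or [SpectraSet]/[SensorTable].
#' @param y numeric 0/1 response; taken from `X` when it carries measurement
#'   IDs and `y` is `NULL`.
#' @param segments list of row-index vectors partitioning the rows (see
#'   [positionSegments()]/[sampleSegments()]).
#' @param nLV number of latent variables (default 2).
#' @param threshold decision threshold (default 0.5).
#' @return list with elements `predictions` ([PredictionSet-class], in
#'   original row order) and `report` ([ValidationReport-class]).
#' @export
segmentedCV <- function(X, y = NULL, segments, nLV = 2L, threshold = 0.5) {
    xy <- .resolveXY(X, y)
    X <- xy$X; y <- xy$y
    n <- nrow(X)
    if (n < 3L)
        stop("at least 3 rows are required for cross-validation")
    segments <- .checkSegments(segments, n)
    yPred <- numeric(n)
    segNames <- if (!is.null(names(segments))) names(segments)
        else as.character(seq_along(segments))
    for (k in seq_along(segments)) {
        hold <- segments[[k]]
        yTrain <- y[-hold]
        if (length(unique(yTrain)) < 2L)
            stop(sprintf(
                "training fold for segment '%s' contains a single class",
                segNames[k]))
        fit <- fitPLSDA(X[-hold, , drop = FALSE], yTrain, nLV = nLV,
            threshold = threshold)
        yPred[hold] <- predictResponse(fit, X[hold, , drop = FALSE])
    }
    pred <- PredictionSet(y, yPred, threshold = threshold)
    scheme <- if (all(lengths(segments) == 1L)) "loo_cv" else "segmented_cv"
    list(predictions = pred, report = .makeReport(scheme, pred, nLV))
}

#' Leave-one-out cross-validation
#'
#' Full LOO CV: [segmentedCV()] with singleton segments (bit-identical pooled
#' predictions by construction).
#'
#' @inheritParams segmentedCV
#' @return as [segmentedCV()], with scheme `"loo_cv"`.
#' @export
looCV <- function(X, y = NULL, nLV = 2L, threshold = 0.5) {
    n <- if (is(X, "MeasurementSet")) nrow(intensityMatrix(X)) else
        nrow(as.matrix(X))
    segmentedCV(X, y, segments = as.list(seq_len(n)), nLV = nLV,
        threshold = threshold)
}

#' Calibration (training-set) statistics
#'
#' Fits on the full data and evaluates on the same data - the optimistic
#' baseline row of a validation table.
#'
#' @inheritParams segmentedCV
#' @return as [segmentedCV()], with scheme `"calibration"`.
#' @export
calibrationReport <- function(X, y = NULL, nLV = 2L, threshold = 0.5) {
    xy <- .resolveXY(X, y)
    fit <- fitPLSDA(xy$X, xy$y, nLV = nLV, threshold = threshold)
    pred <- PredictionSet(xy$y, fitted(fit), threshold = threshold)
    list(predictions = pred, report = .makeReport("calibration", pred, nLV))
}

#' Choose the number of latent variables by cross-validation
#'
#' Evaluates each candidate LV count by segmented-CV DQ2 (the selection
#' criterion) and LOO-CV DQ2 (reported alongside); returns the candidate
#' maximizing the segmented-CV DQ2, breaking ties toward fewer latent
#' variables.
#'
#' @inheritParams segmentedCV
#' @param candidates integer vector of LV counts to try.
#' @return list with elements `nLV` (the selection) and `stats` (a
#'   `data.frame` with columns `nLV`, `segmentedDQ2`, `looDQ2`).
#' @export
chooseNLV <- function(X, y = NULL, candidates, segments, threshold = 0.5) {
    if (!length(candidates))
        stop("'candidates' must be non-empty")
    candidates <- sort(unique(as.integer(candidates)))
    seg <- vapply(candidates, function(a)
        segmentedCV(X, y, segments, nLV = a, threshold = threshold)$
            report@dq2, numeric(1L))
    loo <- vapply(candidates, function(a)
        looCV(X, y, nLV = a, threshold = threshold)$report@dq2, numeric(1L))
    best <- candidates[which.max(seg)]  # first max = fewest LVs on ties
    list(nLV = best,
        stats = data.frame(nLV = candidates, segmentedDQ2 = seg,
            looDQ2 = loo))
}
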