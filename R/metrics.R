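#' @include accessors.R
NULL

#' Confusion counts for a binary discrimination
#'
#' Positives are tumor (class 1): TP = tumor called tumor, TN = normal called
#' normal, FP = normal called tumor, FN = tumor called normal.
#'
#' @param yTrue numeric 0/1 vector of known diagnoses.
#' @param yClass numeric 0/1 vector of assigned classes.
#' @return named integer vector `c(TP, FP, TN, FN)` summing to the number of
#'   evaluated measurements.
#' @examples
#' confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusionCounts <- function(yTrue, yClass) {
    yTrue <- .checkBinary(yTrue)
    yClass <- .checkBinary(yClass)
    if (!length(yTrue))
        stop("empty input")
    if (length(yTrue) != length(yClass))
        stop("'yTrue' and 'yClass' must have equal lengths")
    c(TP = sum(yTrue == 1 & yClass == 1),
      FP = sum(yTrue == 0 & yClass == 1),
      TN = sum(yTrue == 0 & yClass == 0),
      FN = sum(yTrue == 1 & yClass == 0))
}

#' Sensitivity, specificity and accuracy in percent
#'
#' `%Sn = TP / (TP + FN)`, `%Sp = TN / (FP + TN)`,
#' `%Ac = (TP + TN) / (TP + FP + TN + FN)`, each on the 0--100 scale. A zero
#' denominator yields `NA` (undefined), never 0. Values are returned at full
#' precision; reports round half-up to one decimal (see
#' [as.data.frame.ValidationReport()]).
#'
#' @param counts named vector with elements `TP`, `FP`, `TN`, `FN` (as
#'   returned by [confusionCounts()]).
#' @return named numeric vector `c(sn, sp, ac)` in percent.
#' @examples
#' roundHalfUp(snSpAc(c(TP = 19, FP = 1, TN = 11, FN = 2)), 1)
#' @export
snSpAc <- function(counts) {
    stopifnot(all(c("TP", "FP", "TN", "FN") %in% names(counts)))
    tp <- counts[["TP"]]; fp <- counts[["FP"]]
    tn <- counts[["TN"]]; fn <- counts[["FN"]]
    safe <- function(num, den) if (den > 0) 100 * num / den else NA_real_
    c(sn = safe(tp, tp + fn),
      sp = safe(tn, fp + tn),
      ac = safe(tp + tn, tp + fp + tn + fn))
}

.dq2Numeric <- function(yTrue, yPred) {
    yTrue <- .checkBinary(yTrue)
    yPred <- as.numeric(yPred)
    if (length(yTrue) != length(yPred))
        stop("'yTrue' and 'yPred' must have equal lengths")
    if (length(unique(yTrue)) < 2L)
        stop("DQ2 undefined: only one class present in 'yTrue'")
    ybar <- mean(yTrue)
    num <- sum((yTrue - yPred)[yTrue == 0 & yPred > 0]^2) +
           sum((yTrue - yPred)[yTrue == 1 & yPred < 1]^2)
    num / sum((yTrue - ybar)^2)
}

#' @describeIn dq2 Discriminant Q-squared from explicit vectors:
#'   `dq2(yTrue, yPred = ...)`. DQ2 modifies the conventional Q2 so that
#'   correct predictions falling outside the 0--1 coding interval (class-0
#'   predictions below 0, class-1 predictions above 1) contribute nothing to
#'   the residual sum:
#'   \deqn{DQ^2 = 1 - \frac{\sum_{y_i=0,\ \hat y_i>0}(y_i-\hat y_i)^2 +
#'     \sum_{y_i=1,\ \hat y_i<1}(y_i-\hat y_i)^2}{\sum_i (y_i-\bar y)^2}.}
#'   Always at most 1; equals 1 iff every prediction is on the correct side
#'   of its coding bound.
#' @param yPred continuous predicted responses (numeric method).
#' @export
setMethod("dq2", "numeric", function(object, yPred, ...) {
    1 - .dq2Numeric(object, yPred)
})

#' @describeIn dq2 DQ2 of a [PredictionSet].
#' @export
setMethod("dq2", "PredictionSet", function(object, ...) {
    1 - .dq2Numeric(object@yTrue, object@yPred)
})

#' Conventional Q-squared (all residuals counted)
#'
#' `1 - sum((y - yhat)^2) / sum((y - ybar)^2)`; provided as the baseline
#' against which [dq2()] is guaranteed to be no smaller.
#'
#' @param yTrue numeric 0/1 vector.
#' @param yPred continuous predictions.
#' @return scalar Q-squared.
#' @export
q2 <- function(yTrue, yPred) {
    yTrue <- .checkBinary(yTrue)
    if (length(unique(yTrue)) < 2L)
        stop("Q2 undefined: only one class present in 'yTrue'")
    1 - sum((yTrue - yPred)^2) / sum((yTrue - mean(yTrue))^2)
}

## assemble a ValidationReport from pooled predictions
.makeReport <- function(scheme, pred, nLV, nmc = NA_real_) {
    counts <- confusionCounts(pred@yTrue, pred@yClass)
    stats <- snSpAc(counts)
    new("ValidationReport", scheme = scheme,
        counts = vapply(counts, as.integer, integer(1L)),
        dq2 = dq2(pred),
        sn = stats[["sn"]], sp = stats[["sp"]], ac = stats[["ac"]],
        nmc = nmc, nLV = as.integer(nLV), predictions = pred)
}
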