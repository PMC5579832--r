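#' @include AllClasses.R
NULL

#' @rdname accessors
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))

#' @rdname accessors
#' @export
setGeneric("measurementIDs", function(x) standardGeneric("measurementIDs"))

#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname accessors
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))

#' @rdname accessors
#' @export
setGeneric("scores", function(x, ...) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("loadings", function(x, ...) standardGeneric("loadings"))

#' @rdname accessors
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' @rdname accessors
#' @export
setGeneric("nLatent", function(x) standardGeneric("nLatent"))

#' @rdname accessors
#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))

#' @rdname accessors
#' @export
setGeneric("metadata", function(x) standardGeneric("metadata"))

#' Remove measurements matching documented exclusion rules
#'
#' @param x a [SpectraSet] or [SensorTable].
#' @param rules character vector of exclusion patterns (see Details) or an
#'   object returned by [readExclusionList()].
#' @param ... unused.
#' @export
setGeneric("applyExclusions", function(x, rules, ...)
    standardGeneric("applyExclusions"))

#' Discriminant Q-squared (DQ2)
#'
#' @param object a [PredictionSet], or a numeric 0/1 vector of true classes.
#' @param ... for the numeric method, `yPred`, the continuous predictions.
#' @export
setGeneric("dq2", function(object, ...) standardGeneric("dq2"))
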