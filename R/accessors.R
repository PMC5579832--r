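#' @include AllGenerics.R
NULL

## ---- constructors -----------------------------------------------------------

#' Construct a SpectraSet
#'
#' @param values numeric samples-by-wavelengths matrix.
#' @param wavelengths numeric wavelength axis (nm), strictly increasing.
#' @param ids character measurement identifiers, one per row
#'   (e.g. `"T191_3"`, `"N144_Cn_4"`).
#' @param metadata optional list of annotations.
#' @return a [SpectraSet-class] object.
#' @examples
#' s <- SpectraSet(matrix(rnorm(6, 30), 2, 3), c(900, 1000, 1100),
#'                 c("T1_1", "N1_1"))
#' classLabels(s)
#' @export
SpectraSet <- function(values, wavelengths, ids, metadata = list()) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    dimnames(values) <- list(ids, as.character(wavelengths))
    new("SpectraSet", values = values, wavelengths = as.numeric(wavelengths),
        ids = as.character(ids), metadata = metadata)
}

#' Construct a SensorTable
#'
#' @param values numeric samples-by-channels matrix.
#' @param channels ordered channel labels, one per column.
#' @param ids character measurement identifiers, one per row.
#' @param metadata optional list of annotations.
#' @return a [SensorTable-class] object.
#' @export
SensorTable <- function(values, channels, ids, metadata = list()) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    dimnames(values) <- list(ids, channels)
    new("SensorTable", values = values, channels = as.character(channels),
        ids = as.character(ids), metadata = metadata)
}

#' Construct an LEDProfile
#'
#' @param channel channel label (e.g. `"U1"`).
#' @param peak nominal emission maximum in micrometres.
#' @param wavelengths numeric wavelength axis (nm).
#' @param intensity emission intensities; rescaled to maximum 1.
#' @return an [LEDProfile-class] object.
#' @export
LEDProfile <- function(channel, peak, wavelengths, intensity) {
    intensity <- as.numeric(intensity)
    if (!length(intensity) || max(intensity) <= 0)
        stop("LED intensity must contain positive values")
    new("LEDProfile", channel = as.character(channel), peak = as.numeric(peak),
        wavelengths = as.numeric(wavelengths),
        intensity = intensity / max(intensity))
}

#' Construct a PredictionSet
#'
#' `yClass` is derived from `yPred` and `threshold` (class 1 iff
#' `yPred >= threshold`) unless given explicitly.
#'
#' @param yTrue numeric 0/1 vector of known diagnoses.
#' @param yPred continuous predicted responses.
#' @param threshold decision threshold (default 0.5).
#' @param yClass optional explicit 0/1 class assignments.
#' @return a [PredictionSet-class] object.
#' @examples
#' PredictionSet(c(0, 1), c(0.1, 0.9))
#' @export
PredictionSet <- function(yTrue, yPred, threshold = 0.5, yClass = NULL) {
    if (is.null(yClass))
        yClass <- as.numeric(yPred >= threshold)
    new("PredictionSet", yTrue = as.numeric(yTrue), yPred = as.numeric(yPred),
        yClass = as.numeric(yClass), threshold = as.numeric(threshold))
}

## ---- accessors --------------------------------------------------------------

#' Accessors for nirled S4 objects
#'
#' `intensityMatrix()` returns the numeric data matrix of a [SpectraSet] or
#' [SensorTable]; `measurementIDs()` the per-row identifiers; `classLabels()`
#' the 0/1 diagnosis codes derived from the identifiers (N -> 0, T -> 1);
#' `wavelengths()` the nm axis; `channels()` the sensor channel labels;
#' `scores()`, `loadings()`, `explainedVariance()`, `nLatent()` and
#' `threshold()` the corresponding model components.
#'
#' @param x,object a nirled S4 object.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("intensityMatrix", "MeasurementSet", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("measurementIDs", "MeasurementSet", function(x) x@ids)

#' @rdname accessors
#' @export
setMethod("classLabels", "MeasurementSet", function(x) {
    info <- parseMeasurementID(x@ids)
    as.numeric(info$tissueClass == "T")
})

#' @rdname accessors
#' @export
setMethod("metadata", "MeasurementSet", function(x) x@metadata)

#' @rdname accessors
#' @export
setMethod("wavelengths", "SpectraSet", function(x) x@wavelengths)

#' @rdname accessors
#' @export
setMethod("wavelengths", "LEDProfile", function(x) x@wavelengths)

#' @rdname accessors
#' @export
setMethod("channels", "SensorTable", function(x) x@channels)

#' @rdname accessors
#' @export
setMethod("channels", "LEDProfile", function(x) x@channel)

#' @rdname accessors
#' @export
setMethod("dim", "MeasurementSet", function(x) dim(x@values))

#' Row subsetting of measurement containers
#'
#' `x[i]` (or `x[i, ]`) keeps the selected measurements; columns are never
#' subset, so the wavelength axis / channel set is preserved.
#'
#' @param x a [SpectraSet] or [SensorTable].
#' @param i numeric, logical or character (measurement ID) row index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "MeasurementSet", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i))
        i <- match(i, x@ids)
    x@values <- x@values[i, , drop = FALSE]
    x@ids <- x@ids[i]
    validObject(x)
    x
})

#' @rdname accessors
#' @export
setMethod("scores", "PCAModel", function(x, ...) x@scores)

#' @rdname accessors
#' @export
setMethod("scores", "PLSDAModel", function(x, ...) x@scores)

#' @rdname accessors
#' @export
setMethod("loadings", "PCAModel", function(x, ...) x@loadings)

#' @rdname accessors
#' @export
setMethod("loadings", "PLSDAModel", function(x, ...) x@xLoadings)

#' @rdname accessors
#' @export
setMethod("explainedVariance", "PCAModel", function(x) x@explainedVariance)

#' @rdname accessors
#' @export
setMethod("nLatent", "PLSDAModel", function(x) x@nLV)

#' @rdname accessors
#' @export
setMethod("threshold", "PLSDAModel", function(x) x@threshold)

#' @rdname accessors
#' @export
setMethod("threshold", "PredictionSet", function(x) x@threshold)

#' @rdname accessors
#' @importFrom stats coef
#' @export
setMethod("coef", "PLSDAModel", function(object, ...) object@coefficients)

#' @rdname accessors
#' @importFrom stats fitted
#' @export
setMethod("fitted", "PLSDAModel", function(object, ...) object@fitted)

#' Turn a ValidationReport into a one-row data.frame
#'
#' Columns follow the conventional reporting layout: scheme, DQ2, TP, FP, TN,
#' FN, %Sn, %Sp, %Ac (percentages rounded half-up to one decimal), NMC, nLV.
#'
#' @param x a [ValidationReport-class] object.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return a one-row `data.frame`.
#' @export
as.data.frame.ValidationReport <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
    data.frame(
        scheme = x@scheme,
        DQ2 = x@dq2,
        TP = x@counts[["TP"]], FP = x@counts[["FP"]],
        TN = x@counts[["TN"]], FN = x@counts[["FN"]],
        Sn = roundHalfUp(x@sn, 1L),
        Sp = roundHalfUp(x@sp, 1L),
        Ac = roundHalfUp(x@ac, 1L),
        NMC = x@nmc,
        nLV = x@nLV,
        row.names = NULL)
}
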