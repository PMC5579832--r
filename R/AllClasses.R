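#' @import methods
NULL

## ---- measurement containers -------------------------------------------------

#' Virtual parent of row-wise measurement containers
#'
#' A samples-by-variables numeric matrix whose rows carry measurement
#' identifiers of the form `T191_3` / `N144_Cn_4` (tissue class, patient,
#' optional position, repeat index). [SpectraSet] and [SensorTable] extend it.
#'
#' @slot values numeric matrix, one row per measurement.
#' @slot ids character vector of measurement identifiers, one per row.
#' @slot metadata list of free-form annotations (e.g. exclusion reports).
#'
#' @name MeasurementSet-class
#' @aliases MeasurementSet
#' @exportClass MeasurementSet
setClass("MeasurementSet",
    representation("VIRTUAL",
        values = "matrix",
        ids = "character",
        metadata = "list"),
    prototype(metadata = list()))

.validMeasurementSet <- function(object) {
    msg <- character()
    v <- object@values
    if (!is.numeric(v))
        msg <- c(msg, "'values' must be a numeric matrix")
    if (nrow(v) != length(object@ids))
        msg <- c(msg, "number of rows must equal number of measurement IDs")
    if (anyDuplicated(object@ids))
        msg <- c(msg, sprintf("duplicate measurement IDs: %s",
            paste(unique(object@ids[duplicated(object@ids)]), collapse = ", ")))
    if (length(object@ids)) {
        ok <- tryCatch({ parseMeasurementID(object@ids); TRUE },
            error = function(e) conditionMessage(e))
        if (!isTRUE(ok)) msg <- c(msg, ok)
    }
    if (length(msg)) msg else TRUE
}

setValidity("MeasurementSet", .validMeasurementSet)

#' Full-resolution diffuse-reflectance spectra
#'
#' Samples-by-wavelengths reflectance matrix (percent of a white standard, or
#' detector volts) with a strictly increasing wavelength axis in nm and per-row
#' measurement identifiers.
#'
#' @slot wavelengths numeric vector (nm), strictly increasing, one per column.
#'
#' @seealso [SpectraSet()] for the constructor, [simulateTissueSpectra()],
#'   [readSpectra()].
#' @name SpectraSet-class
#' @aliases SpectraSet-class
#' @exportClass SpectraSet
setClass("SpectraSet",
    contains = "MeasurementSet",
    representation(wavelengths = "numeric"))

setValidity("SpectraSet", function(object) {
    msg <- character()
    if (ncol(object@values) != length(object@wavelengths))
        msg <- c(msg, "number of columns must equal number of wavelengths")
    if (length(object@wavelengths) > 1L && any(diff(object@wavelengths) <= 0))
        msg <- c(msg, "'wavelengths' must be strictly increasing")
    if (length(msg)) msg else TRUE
})

#' Multichannel sensor intensity table
#'
#' Samples-by-channels matrix of simulated or measured sensor intensities,
#' one column per LED channel (U1--U4 for the four-LED design).
#'
#' @slot channels ordered character vector of channel labels, one per column.
#'
#' @seealso [SensorTable()] for the constructor, [simulateSensor()].
#' @name SensorTable-class
#' @aliases SensorTable-class
#' @exportClass SensorTable
setClass("SensorTable",
    contains = "MeasurementSet",
    representation(channels = "character"))

setValidity("SensorTable", function(object) {
    msg <- character()
    if (ncol(object@values) != length(object@channels))
        msg <- c(msg, "number of columns must equal number of channels")
    if (anyDuplicated(object@channels))
        msg <- c(msg, "channel labels must be unique")
    if (length(msg)) msg else TRUE
})

## ---- LED emission profile ---------------------------------------------------

#' Emission profile of one sensor LED
#'
#' Normalized emission spectrum of a single light-emitting diode, with its
#' nominal peak wavelength in micrometres and a channel label. The four-LED
#' set of the sensor maps peaks to channels as 0.94 um -> U4, 1.17 um -> U3,
#' 1.30 um -> U1, 1.44 um -> U2.
#'
#' @slot channel channel label, e.g. `"U1"`.
#' @slot peak nominal emission maximum in micrometres.
#' @slot wavelengths numeric vector (nm) on which the emission is tabulated.
#' @slot intensity non-negative emission intensities, maximum exactly 1.
#'
#' @seealso [generateLEDProfiles()], [simulateSensor()].
#' @name LEDProfile-class
#' @aliases LEDProfile-class
#' @exportClass LEDProfile
setClass("LEDProfile",
    representation(
        channel = "character",
        peak = "numeric",
        wavelengths = "numeric",
        intensity = "numeric"))

setValidity("LEDProfile", function(object) {
    msg <- character()
    if (length(object@channel) != 1L)
        msg <- c(msg, "'channel' must be a single label")
    if (length(object@peak) != 1L || object@peak <= 0)
        msg <- c(msg, "'peak' must be a single positive value (micrometres)")
    if (length(object@wavelengths) != length(object@intensity))
        msg <- c(msg, "'wavelengths' and 'intensity' lengths differ")
    if (any(object@intensity < 0))
        msg <- c(msg, "'intensity' must be non-negative")
    if (length(object@intensity) &&
        abs(max(object@intensity) - 1) > 1e-12)
        msg <- c(msg, "'intensity' must be normalized to maximum 1")
    if (length(object@wavelengths) > 1L && any(diff(object@wavelengths) <= 0))
        msg <- c(msg, "'wavelengths' must be strictly increasing")
    if (length(msg)) msg else TRUE
})

## ---- models -----------------------------------------------------------------

#' Principal component analysis model
#'
#' Mean-centered PCA decomposition with orthonormal loadings; used for
#' exploratory inspection of sensor data (outlier and cluster detection).
#'
#' @slot loadings variables-by-components orthonormal matrix.
#' @slot scores samples-by-components score matrix (`centered X %*% loadings`).
#' @slot explainedVariance fraction of total variance per component,
#'   non-increasing, summing to at most 1.
#' @slot columnMeans training column means.
#'
#' @seealso [fitPCA()].
#' @name PCAModel-class
#' @aliases PCAModel-class
#' @exportClass PCAModel
setClass("PCAModel",
    representation(
        loadings = "matrix",
        scores = "matrix",
        explainedVariance = "numeric",
        columnMeans = "numeric"))

setValidity("PCAModel", function(object) {
    msg <- character()
    L <- object@loadings
    if (ncol(L) != ncol(object@scores))
        msg <- c(msg, "loadings and scores disagree on component count")
    if (ncol(L)) {
        G <- crossprod(L)
        if (max(abs(G - diag(ncol(L)))) > 1e-8)
            msg <- c(msg, "loadings columns must be orthonormal")
    }
    ev <- object@explainedVariance
    if (length(ev) > 1L && any(diff(ev) > 1e-12))
        msg <- c(msg, "'explainedVariance' must be non-increasing")
    if (sum(ev) > 1 + 1e-8)
        msg <- c(msg, "'explainedVariance' must sum to at most 1")
    if (length(msg)) msg else TRUE
})

#' Fitted PLS-DA discrimination model
#'
#' A PLS1 regression of the 0/1 class code (0 = normal, 1 = tumor) on
#' mean-centered predictors, fitted by NIPALS, together with the decision
#' threshold applied to the continuous predicted response.
#'
#' @slot nLV number of latent variables retained.
#' @slot xWeights variables-by-LV weight matrix W (unit columns).
#' @slot xLoadings variables-by-LV loading matrix P.
#' @slot scores samples-by-LV training score matrix T (mutually orthogonal
#'   columns).
#' @slot coefficients regression vector b mapping centered predictors to the
#'   centered response.
#' @slot xMeans,yMean training means; predictions are
#'   `(x - xMeans) %*% b + yMean`.
#' @slot threshold decision threshold on the predicted response (class 1 iff
#'   response >= threshold).
#' @slot fitted training-set fitted responses.
#'
#' @seealso [fitPLSDA()], [predictResponse()], [predictClass()].
#' @name PLSDAModel-class
#' @aliases PLSDAModel-class
#' @exportClass PLSDAModel
setClass("PLSDAModel",
    representation(
        nLV = "integer",
        xWeights = "matrix",
        xLoadings = "matrix",
        scores = "matrix",
        coefficients = "numeric",
        xMeans = "numeric",
        yMean = "numeric",
        threshold = "numeric",
        fitted = "numeric"))

setValidity("PLSDAModel", function(object) {
    msg <- character()
    Tm <- object@scores
    if (ncol(Tm) != object@nLV)
        msg <- c(msg, "score matrix column count must equal nLV")
    if (ncol(Tm) > 1L) {
        G <- crossprod(Tm)
        off <- G - diag(diag(G), ncol(G))
        if (max(abs(off)) > 1e-6 * max(diag(G)))
            msg <- c(msg, "score vectors must be mutually orthogonal")
    }
    if (length(object@coefficients) != nrow(object@xWeights))
        msg <- c(msg, "'coefficients' length must match variable count")
    if (length(msg)) msg else TRUE
})

## ---- predictions and validation reports -------------------------------------

#' Paired true/predicted responses for a discrimination run
#'
#' Holds the known 0/1 diagnoses, the continuous PLS-DA predicted responses,
#' and the thresholded class assignments for one (possibly pooled) prediction
#' exercise.
#'
#' @slot yTrue numeric 0/1 vector of known diagnoses.
#' @slot yPred continuous predicted responses (not clipped to `[0, 1]`).
#' @slot yClass 0/1 class assignments, `yPred >= threshold`.
#' @slot threshold the decision threshold used.
#'
#' @seealso [PredictionSet()], [dq2()], [confusionCounts()].
#' @name PredictionSet-class
#' @aliases PredictionSet-class
#' @exportClass PredictionSet
setClass("PredictionSet",
    representation(
        yTrue = "numeric",
        yPred = "numeric",
        yClass = "numeric",
        threshold = "numeric"))

setValidity("PredictionSet", function(object) {
    msg <- character()
    n <- length(object@yTrue)
    if (length(object@yPred) != n || length(object@yClass) != n)
        msg <- c(msg, "'yTrue', 'yPred' and 'yClass' must have equal lengths")
    if (!all(object@yTrue %in% c(0, 1)))
        msg <- c(msg, "'yTrue' must be coded 0/1")
    if (!all(object@yClass %in% c(0, 1)))
        msg <- c(msg, "'yClass' must be coded 0/1")
    if (length(object@threshold) == 1L && is.finite(object@threshold) &&
        !all(object@yClass == as.numeric(object@yPred >= object@threshold)))
        msg <- c(msg, "'yClass' inconsistent with the threshold rule")
    if (length(msg)) msg else TRUE
})

#' Discrimination statistics for one validation scheme
#'
#' Confusion counts and derived statistics (DQ2, sensitivity, specificity,
#' accuracy in percent, and - for random-subset contexts - the mean number of
#' misclassified measurements, NMC) for a calibration or validation run.
#'
#' @slot scheme one of `"calibration"`, `"loo_cv"`, `"segmented_cv"`, `"rsv"`.
#' @slot counts named integer vector `c(TP, FP, TN, FN)`; cumulative over
#'   iterations for the `"rsv"` scheme.
#' @slot dq2 discriminant Q-squared on the (pooled) predictions.
#' @slot sn,sp,ac sensitivity, specificity, accuracy in percent (0--100);
#'   `NA` when a denominator is zero.
#' @slot nmc mean number of misclassified measurements per iteration
#'   (FP + FN; `NA` outside random-subset contexts).
#' @slot nLV number of latent variables used.
#' @slot predictions the pooled [PredictionSet], or `NULL`.
#'
#' @seealso [looCV()], [segmentedCV()], [randomSubsetValidation()],
#'   [writeValidationReports()].
#' @name ValidationReport-class
#' @aliases ValidationReport-class
#' @exportClass ValidationReport
setClass("ValidationReport",
    representation(
        scheme = "character",
        counts = "integer",
        dq2 = "numeric",
        sn = "numeric",
        sp = "numeric",
        ac = "numeric",
        nmc = "numeric",
        nLV = "integer",
        predictions = "ANY"))

setValidity("ValidationReport", function(object) {
    msg <- character()
    if (!object@scheme %in% c("calibration", "loo_cv", "segmented_cv", "rsv"))
        msg <- c(msg, "unknown validation scheme")
    if (!identical(names(object@counts), c("TP", "FP", "TN", "FN")))
        msg <- c(msg, "'counts' must be named TP, FP, TN, FN")
    if (any(!is.na(object@counts) & object@counts < 0))
        msg <- c(msg, "'counts' must be non-negative")
    for (s in c("sn", "sp", "ac")) {
        v <- slot(object, s)
        if (!is.na(v) && (v < 0 || v > 100))
            msg <- c(msg, sprintf("'%s' must lie in [0, 100]", s))
    }
    if (!is.na(object@dq2) && object@dq2 > 1 + 1e-12)
        msg <- c(msg, "'dq2' cannot exceed 1")
    if (length(msg)) msg else TRUE
})

## ---- synthetic-data configuration -------------------------------------------

#' Configuration for the synthetic tissue-spectra generator
#'
#' Parameters of the generative model behind [simulateTissueSpectra()]:
#' a grouped design (patient -> tumor/normal sample -> position -> repeat)
#' of diffuse-reflectance spectra built from a per-sample baseline offset,
#' negative Gaussian absorption bands (water near 970 and 1450 nm, lipid near
#' 1210 nm) scaled by a per-sample contrast, and i.i.d. measurement noise.
#' Tumor samples receive an additive offset shift, a multiplicative contrast
#' gain, and inflated between-measurement variance.
#'
#' @slot nPatients number of patients; each contributes one tumor (T) and one
#'   normal (N) sample.
#' @slot positionsPerSample measurement positions per sample (the first is the
#'   sample-center position `Cn`, the rest grid cells).
#' @slot repeatsPerPosition repeated measurements per position.
#' @slot wavelengthGrid wavelength axis in nm, strictly increasing.
#' @slot bandCenters,bandWidths,bandDepths absorption-band centers (nm),
#'   Gaussian widths (standard deviations, nm) and depths (reflectance-%).
#' @slot baseOffset mean baseline reflectance of normal tissue (%).
#' @slot sampleOffsetSD,positionOffsetSD standard deviations (%) of the
#'   per-sample and per-position random baseline effects.
#' @slot contrastJitterSD log-scale standard deviation of the per-sample
#'   multiplicative contrast jitter.
#' @slot classOffsetShift additive offset of tumor over normal tissue (%).
#' @slot classContrastFactor multiplicative band-contrast gain for tumor
#'   (1 = no gain).
#' @slot tumorVarianceInflation variance inflation factor (>= 1) applied to
#'   all tumor random effects and noise.
#' @slot noiseSD per-repeat measurement noise standard deviation (%).
#' @slot seed integer seed; identical seeds give bit-identical datasets.
#'
#' @seealso [TissueSimConfig()], [simulateTissueSpectra()].
#' @name TissueSimConfig-class
#' @aliases TissueSimConfig-class
#' @exportClass TissueSimConfig
setClass("TissueSimConfig",
    representation(
        nPatients = "integer",
        positionsPerSample = "integer",
        repeatsPerPosition = "integer",
        wavelengthGrid = "numeric",
        bandCenters = "numeric",
        bandWidths = "numeric",
        bandDepths = "numeric",
        baseOffset = "numeric",
        sampleOffsetSD = "numeric",
        positionOffsetSD = "numeric",
        contrastJitterSD = "numeric",
        classOffsetShift = "numeric",
        classContrastFactor = "numeric",
        tumorVarianceInflation = "numeric",
        noiseSD = "numeric",
        seed = "integer"))

setValidity("TissueSimConfig", function(object) {
    msg <- character()
    if (object@nPatients < 1L || object@positionsPerSample < 1L ||
        object@repeatsPerPosition < 1L)
        msg <- c(msg, "design counts must all be at least 1")
    g <- object@wavelengthGrid
    if (length(g) < 2L || any(diff(g) <= 0))
        msg <- c(msg, "'wavelengthGrid' must be strictly increasing")
    if (length(object@bandCenters) != length(object@bandWidths) ||
        length(object@bandCenters) != length(object@bandDepths))
        msg <- c(msg, "band centers, widths and depths must have equal lengths")
    if (any(object@bandWidths <= 0))
        msg <- c(msg, "all band widths must be positive")
    if (object@noiseSD < 0)
        msg <- c(msg, "'noiseSD' must be non-negative")
    if (object@tumorVarianceInflation < 1)
        msg <- c(msg, "'tumorVarianceInflation' must be at least 1")
    if (object@sampleOffsetSD < 0 || object@positionOffsetSD < 0 ||
        object@contrastJitterSD < 0)
        msg <- c(msg, "random-effect standard deviations must be non-negative")
    if (length(msg)) msg else TRUE
})
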