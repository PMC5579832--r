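#' @include pipeline.R
NULL

setMethod("show", "SpectraSet", function(object) {
    wl <- object@wavelengths
    cat(sprintf("SpectraSet: %d measurements x %d wavelengths (%.1f-%.1f nm)\n",
        nrow(object@values), length(wl), min(wl), max(wl)))
    y <- tryCatch(classLabels(object), error = function(e) NULL)
    if (!is.null(y))
        cat(sprintf("  classes: %d tumor (T), %d normal (N)\n",
            sum(y == 1), sum(y == 0)))
    ids <- object@ids
    cat(sprintf("  ids: %s%s\n", paste(utils::head(ids, 3L), collapse = ", "),
        if (length(ids) > 3L) ", ..." else ""))
    if (length(object@metadata$excluded))
        cat(sprintf("  excluded: %d measurement(s)\n",
            length(object@metadata$excluded)))
})

setMethod("show", "SensorTable", function(object) {
    cat(sprintf("SensorTable: %d measurements x %d channels (%s)\n",
        nrow(object@values), length(object@channels),
        paste(object@channels, collapse = ", ")))
    y <- tryCatch(classLabels(object), error = function(e) NULL)
    if (!is.null(y))
        cat(sprintf("  classes: %d tumor (T), %d normal (N)\n",
            sum(y == 1), sum(y == 0)))
})

setMethod("show", "LEDProfile", function(object) {
    cat(sprintf("LEDProfile %s: peak %.2f um, support %.0f-%.0f nm (%d points)\n",
        object@channel, object@peak, min(object@wavelengths),
        max(object@wavelengths), length(object@wavelengths)))
})

setMethod("show", "PCAModel", function(object) {
    ev <- object@explainedVariance
    cat(sprintf("PCAModel: %d component(s) over %d variables\n",
        ncol(object@loadings), nrow(object@loadings)))
    cat(sprintf("  explained variance: %s\n",
        paste(sprintf("%.1f%%", 100 * ev), collapse = ", ")))
})

setMethod("show", "PLSDAModel", function(object) {
    cat(sprintf("PLSDAModel: %d latent variable(s), %d predictor(s)\n",
        object@nLV, length(object@coefficients)))
    cat(sprintf("  threshold %.2f (class 1 = tumor iff response >= threshold)\n",
        object@threshold))
})

setMethod("show", "PredictionSet", function(object) {
    cat(sprintf("PredictionSet: %d prediction(s), threshold %.2f\n",
        length(object@yTrue), object@threshold))
    print(confusionCounts(object@yTrue, object@yClass))
})

setMethod("show", "ValidationReport", function(object) {
    cat(sprintf("ValidationReport [%s]\n", object@scheme))
    print(as.data.frame(object), row.names = FALSE)
})

setMethod("show", "TissueSimConfig", function(object) {
    cat(sprintf(paste0("TissueSimConfig: %d patient(s) x 2 samples x %d ",
        "position(s) x %d repeat(s)\n"), object@nPatients,
        object@positionsPerSample, object@repeatsPerPosition))
    cat(sprintf("  grid: %d points, %.1f-%.1f nm; seed %d\n",
        length(object@wavelengthGrid), min(object@wavelengthGrid),
        max(object@wavelengthGrid), object@seed))
    cat(sprintf("  tumor effects: offset +%.1f%%, contrast x%.2f, variance x%.1f\n",
        object@classOffsetShift, object@classContrastFactor,
        object@tumorVarianceInflation))
})
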