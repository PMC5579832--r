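#' @include permutation-test.R
NULL

#' Write a set of validation reports as one CSV table
#'
#' One row per report, in the conventional column layout (scheme, DQ2, TP,
#' FP, TN, FN, %Sn, %Sp, %Ac, NMC, nLV); percentages rounded half-up to one
#' decimal.
#'
#' @param reports a list of [ValidationReport-class] objects (or results of
#'   [segmentedCV()]/[looCV()]/[calibrationReport()], whose `$report` is
#'   taken).
#' @param path output CSV path.
#' @return invisibly, the assembled `data.frame`.
#' @export
writeValidationReports <- function(reports, path) {
    rows <- lapply(reports, function(r) {
        if (is.list(r) && !is.null(r$report))
            r <- r$report
        as.data.frame(r)
    })
    df <- do.call(rbind, rows)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
        fileEncoding = "UTF-8")
    invisible(df)
}

.defaultRunConfig <- function() {
    list(
        simulation = list(),        # TissueSimConfig() arguments
        spectraFile = NULL,         # alternative to simulation
        leds = list(peaks = c(0.94, 1.17, 1.30, 1.44), fwhm = 60),
        ledFile = NULL,
        preprocessing = "raw",      # raw | sg2 | snv (full spectra model)
        exclusions = character(),
        nLV = 2L,
        threshold = 0.5,
        validation = list(fraction = 0.15, iterations = 1000L,
            permutations = 100L, segmentBy = "position"),
        seed = 1L,
        outputDir = NULL)
}

#' Load a pipeline run configuration
#'
#' Reads YAML (or JSON - valid JSON is valid YAML) and fills unspecified
#' fields with package defaults.
#'
#' @param path path to a YAML/JSON configuration file, or a named list.
#' @return a complete configuration list.
#' @export
readRunConfig <- function(path) {
    user <- if (is.character(path)) yaml::read_yaml(path) else
        as.list(path)
    cfg <- .defaultRunConfig()
    for (nm in names(user)) {
        if (nm %in% c("validation", "leds") && is.list(user[[nm]])) {
            for (sub in names(user[[nm]]))
                cfg[[nm]][[sub]] <- user[[nm]][[sub]]
        } else {
            cfg[[nm]] <- user[[nm]]
        }
    }
    cfg
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            call. = FALSE))
}

#' Run the full sensor-development analysis
#'
#' Orchestrates the end-to-end workflow: obtain spectra (synthetic or from
#' file), apply documented exclusions, simulate the LED sensor, fit the
#' PLS-DA model, run the validation battery (calibration, leave-one-out CV,
#' segmented CV, random-subset validation) and the label-permutation test,
#' and write all tabular outputs plus a manifest to `outputDir`. Every stage
#' is a pure function of the inputs, configuration and seed, so a repeated
#' run with the same configuration produces byte-identical outputs.
#'
#' Output files: `sensor_table.csv`, `coefficients.csv`, `scores.csv`,
#' `reports.csv` (one row per scheme), `permutation_nmc.csv` (sorted NMC,
#' original first) and `manifest.json` (configuration, its MD5 hash, seed,
#' exclusion report and row counts).
#'
#' @param config a configuration list or a YAML/JSON file path (see
#'   [readRunConfig()]).
#' @param outputDir output directory (created if missing); overrides any
#'   `outputDir` in the configuration. `NULL` writes nothing.
#' @return invisibly, a list with the sensor table, fitted model, reports,
#'   permutation-test result and the configuration used.
#' @export
runAnalysis <- function(config = list(), outputDir = NULL) {
    cfg <- readRunConfig(config)
    if (!is.null(outputDir))
        cfg$outputDir <- outputDir

    spectra <- .stage("input", {
        if (!is.null(cfg$spectraFile)) {
            readSpectra(cfg$spectraFile)
        } else {
            sim <- cfg$simulation
            if (is.null(sim$seed))
                sim$seed <- cfg$seed
            simulateTissueSpectra(do.call(TissueSimConfig, sim))
        }
    })

    if (length(cfg$exclusions))
        spectra <- .stage("exclusions",
            applyExclusions(spectra, cfg$exclusions))

    leds <- .stage("leds", {
        if (!is.null(cfg$ledFile))
            readLEDProfiles(cfg$ledFile)
        else
            generateLEDProfiles(peaks = cfg$leds$peaks,
                fwhm = cfg$leds$fwhm, grid = wavelengths(spectra))
    })

    sensor <- .stage("sensor", simulateSensor(spectra, leds))

    ## the modeled matrix: sensor channels, mean-centered inside the fits;
    ## cfg$preprocessing applies to the optional full-spectra model matrix
    y <- classLabels(sensor)
    fit <- .stage("fit",
        fitPLSDA(sensor, y, nLV = cfg$nLV, threshold = cfg$threshold))

    v <- cfg$validation
    segments <- .stage("segments", switch(v$segmentBy,
        position = positionSegments(measurementIDs(sensor)),
        sample = sampleSegments(measurementIDs(sensor)),
        stop("'validation$segmentBy' must be 'position' or 'sample'")))

    reports <- .stage("validate", list(
        calibration = calibrationReport(sensor, y, nLV = cfg$nLV,
            threshold = cfg$threshold)$report,
        loo_cv = looCV(sensor, y, nLV = cfg$nLV,
            threshold = cfg$threshold)$report,
        segmented_cv = segmentedCV(sensor, y, segments, nLV = cfg$nLV,
            threshold = cfg$threshold)$report,
        rsv = randomSubsetValidation(sensor, y, fraction = v$fraction,
            iterations = v$iterations, nLV = cfg$nLV,
            threshold = cfg$threshold, seed = cfg$seed)))

    pt <- .stage("permute", permutationTest(sensor, y,
        nPermutations = v$permutations, fraction = v$fraction,
        iterations = v$iterations, nLV = cfg$nLV,
        threshold = cfg$threshold, seed = cfg$seed))

    if (!is.null(cfg$outputDir)) .stage("output", {
        dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
        out <- function(f) file.path(cfg$outputDir, f)
        writeSensorTable(sensor, out("sensor_table.csv"))
        utils::write.csv(data.frame(channel = channels(sensor),
            coefficient = coef(fit)), out("coefficients.csv"),
            row.names = FALSE, quote = FALSE)
        utils::write.csv(data.frame(id = measurementIDs(sensor),
            scores(fit)), out("scores.csv"), row.names = FALSE,
            quote = FALSE)
        writeValidationReports(reports, out("reports.csv"))
        utils::write.csv(data.frame(
            permutation = c(0L, seq_along(pt$nmcPermuted)),
            nmc = c(pt$nmcOriginal, pt$nmcPermuted)),
            out("permutation_nmc.csv"), row.names = FALSE, quote = FALSE)
        ## hash the analysis-relevant configuration (output location is
        ## not part of the analysis identity)
        cfgFile <- out("config.json")
        jsonlite::write_json(cfg[setdiff(names(cfg), "outputDir")], cfgFile,
            auto_unbox = TRUE, digits = NA, null = "null")
        manifest <- list(
            configHash = unname(tools::md5sum(cfgFile)),
            seed = cfg$seed,
            nMeasurements = nrow(intensityMatrix(sensor)),
            excluded = metadata(sensor)$excluded,
            permutationPass = pt$pass)
        jsonlite::write_json(manifest, out("manifest.json"),
            auto_unbox = TRUE, digits = NA, null = "null")
    })

    invisible(list(spectra = spectra, sensor = sensor, leds = leds,
        model = fit, reports = reports, permutation = pt, config = cfg))
}
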