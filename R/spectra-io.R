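#' @include accessors.R
NULL

## One CSV dialect, no sniffing: UTF-8, comma-separated, first column "id"
## holding measurement identifiers, remaining column headers numeric
## wavelengths (nm) for spectra or channel labels for sensor tables.

.readMatrixCSV <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
        fileEncoding = "UTF-8")
    if (ncol(df) < 2L)
        stop(sprintf("'%s': expected an id column plus data columns", path))
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
        stop(sprintf("'%s': duplicate measurement IDs: %s", path,
            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    vals <- df[, -1L, drop = FALSE]
    nonnum <- !vapply(vals, is.numeric, logical(1L))
    if (any(nonnum))
        stop(sprintf("'%s': non-numeric cells in column(s) %s", path,
            paste(names(vals)[nonnum], collapse = ", ")))
    if (anyNA(vals))
        stop(sprintf("'%s': missing values are not allowed", path))
    list(ids = ids, values = as.matrix(vals), colnames = colnames(vals))
}

.writeMatrixCSV <- function(values, ids, headers, path) {
    df <- data.frame(id = ids, values, check.names = FALSE,
        stringsAsFactors = FALSE)
    colnames(df) <- c("id", headers)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
        fileEncoding = "UTF-8")
    invisible(path)
}

#' Read / write diffuse-reflectance spectra
#'
#' The CSV dialect is fixed: UTF-8, comma separators, a first column `id`
#' with measurement identifiers, and one numeric column per wavelength whose
#' header is the wavelength in nm. Values round-trip losslessly up to float
#' formatting (15 significant digits).
#'
#' @param path file path.
#' @return `readSpectra()` returns a [SpectraSet-class];
#'   `writeSpectra()` invisibly returns `path`.
#' @examples
#' s <- SpectraSet(matrix(1:6 + 0.5, 2, 3), c(900, 1000, 1100),
#'                 c("T1_1", "N1_1"))
#' f <- tempfile(fileext = ".csv")
#' writeSpectra(s, f)
#' identical(wavelengths(readSpectra(f)), c(900, 1000, 1100))
#' @export
readSpectra <- function(path) {
    raw <- .readMatrixCSV(path)
    wl <- suppressWarnings(as.numeric(raw$colnames))
    if (anyNA(wl))
        stop(sprintf("'%s': wavelength headers must be numeric (offending: %s)",
            path, paste(raw$colnames[is.na(wl)], collapse = ", ")))
    SpectraSet(raw$values, wl, raw$ids)
}

#' @rdname readSpectra
#' @param x a [SpectraSet] (for `writeSpectra`) or [SensorTable]
#'   (for `writeSensorTable`).
#' @export
writeSpectra <- function(x, path) {
    stopifnot(is(x, "SpectraSet"))
    .writeMatrixCSV(format(x@values, digits = 15L, trim = TRUE,
        scientific = FALSE), x@ids, as.character(x@wavelengths), path)
}

#' @rdname readSpectra
#' @export
readSensorTable <- function(path) {
    raw <- .readMatrixCSV(path)
    SensorTable(raw$values, raw$colnames, raw$ids)
}

#' @rdname readSpectra
#' @export
writeSensorTable <- function(x, path) {
    stopifnot(is(x, "SensorTable"))
    .writeMatrixCSV(format(x@values, digits = 15L, trim = TRUE,
        scientific = FALSE), x@ids, x@channels, path)
}

#' Read / write LED emission profiles
#'
#' Profiles are stored in long CSV form with columns `channel`, `peak_um`,
#' `wavelength_nm`, `intensity`.
#'
#' @param path file path.
#' @param leds list of [LEDProfile-class] objects.
#' @return `readLEDProfiles()` returns a named list of [LEDProfile-class]
#'   objects in file order; `writeLEDProfiles()` invisibly returns `path`.
#' @export
readLEDProfiles <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
        fileEncoding = "UTF-8")
    need <- c("channel", "peak_um", "wavelength_nm", "intensity")
    if (!all(need %in% names(df)))
        stop(sprintf("'%s': expected columns %s", path,
            paste(need, collapse = ", ")))
    out <- lapply(split(df, factor(df$channel, levels = unique(df$channel))),
        function(d) LEDProfile(d$channel[1L], d$peak_um[1L],
            d$wavelength_nm, d$intensity))
    out[order(match(names(out), unique(df$channel)))]
}

#' @rdname readLEDProfiles
#' @export
writeLEDProfiles <- function(leds, path) {
    df <- do.call(rbind, lapply(leds, function(l)
        data.frame(channel = l@channel, peak_um = l@peak,
            wavelength_nm = l@wavelengths, intensity = l@intensity)))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
        fileEncoding = "UTF-8")
    invisible(path)
}
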