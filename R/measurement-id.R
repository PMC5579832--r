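#' @include AllClasses.R
NULL

## ID grammar: {T|N}{digits}(_{position})?_{repeat}
## position = alphanumeric code not starting with a digit ("Cn", "B2", ...);
## absent for 2-token IDs ("T191_3").
.ID_REGEX <- "^([TN])([0-9]+)(?:_([A-Za-z][A-Za-z0-9]*))?_([0-9]+)$"

#' Parse measurement identifiers
#'
#' Identifiers encode the tissue class (`T` tumor / `N` normal), the patient
#' ID, an optional measurement position (`Cn` for the sample center or a grid
#' cell such as `C3`), and the ordinal repeat index. `"N144_Cn_4"` is the
#' fourth measurement in the center of the normal sample of patient 144;
#' `"T191_3"` (no position token) is the third measurement on the tumor
#' sample of patient 191.
#'
#' @param ids character vector of identifiers.
#' @return a `data.frame` with one row per identifier and columns
#'   `tissueClass` (`"T"`/`"N"`), `patientID` (integer), `position`
#'   (character, `NA` when absent) and `repeatIndex` (integer).
#' @examples
#' parseMeasurementID(c("N144_Cn_4", "T191_3"))
#' @seealso [formatMeasurementID()] for the inverse.
#' @export
parseMeasurementID <- function(ids) {
    ids <- as.character(ids)
    if (!length(ids) || any(!nzchar(ids)))
        stop("measurement IDs must be non-empty strings")
    m <- regmatches(ids, regexec(.ID_REGEX, ids))
    bad <- lengths(m) == 0L
    if (any(bad)) {
        offender <- ids[bad][1L]
        cls <- substr(offender, 1L, 1L)
        if (!cls %in% c("T", "N"))
            stop(sprintf("malformed measurement ID '%s': unknown tissue class '%s'",
                offender, cls))
        stop(sprintf("malformed measurement ID '%s'", offender))
    }
    parts <- do.call(rbind, m)
    data.frame(
        tissueClass = parts[, 2L],
        patientID = as.integer(parts[, 3L]),
        position = ifelse(nzchar(parts[, 4L]), parts[, 4L], NA_character_),
        repeatIndex = as.integer(parts[, 5L]),
        row.names = NULL, stringsAsFactors = FALSE)
}

#' Format measurement identifiers
#'
#' Inverse of [parseMeasurementID()]: `formatMeasurementID(parseMeasurementID(s))`
#' reproduces `s` for every valid identifier.
#'
#' @param info a `data.frame` with columns `tissueClass`, `patientID`,
#'   `position` (`NA` to omit) and `repeatIndex`.
#' @return character vector of identifiers.
#' @export
formatMeasurementID <- function(info) {
    stopifnot(all(c("tissueClass", "patientID", "repeatIndex") %in% names(info)))
    pos <- if ("position" %in% names(info)) info$position else NA_character_
    ifelse(is.na(pos),
        sprintf("%s%d_%d", info$tissueClass, info$patientID, info$repeatIndex),
        sprintf("%s%d_%s_%d", info$tissueClass, info$patientID, pos,
            info$repeatIndex))
}

#' Sample identifiers ("T151") for a set of measurement IDs
#'
#' @param ids character vector of measurement identifiers.
#' @return character vector, e.g. `"T151"`, one per input.
#' @keywords internal
sampleKey <- function(ids) {
    info <- parseMeasurementID(ids)
    paste0(info$tissueClass, info$patientID)
}

#' Sample+position identifiers ("N144_Cn") for a set of measurement IDs
#'
#' For Series-A-style IDs without a position token the sample key is returned.
#'
#' @param ids character vector of measurement identifiers.
#' @return character vector, one per input.
#' @keywords internal
positionKey <- function(ids) {
    info <- parseMeasurementID(ids)
    key <- paste0(info$tissueClass, info$patientID)
    ifelse(is.na(info$position), key, paste0(key, "_", info$position))
}
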