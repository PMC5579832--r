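#' @include spectra-io.R
NULL

## An exclusion pattern is a measurement-ID fragment:
##   "T151"      -> whole sample (all positions and repeats)
##   "N144_Cn"   -> one measurement position of a sample
##   "N194_5"    -> a single measurement (full ID; trailing digits = repeat)
.classifyPattern <- function(pattern) {
    if (grepl("^[TN][0-9]+$", pattern))
        return("sample")
    if (grepl("^[TN][0-9]+_[A-Za-z][A-Za-z0-9]*$", pattern))
        return("position")
    if (grepl(.ID_REGEX, pattern))
        return("full")
    stop(sprintf("exclusion pattern '%s' is not a valid measurement-ID fragment",
        pattern))
}

.patternMatches <- function(pattern, ids) {
    switch(.classifyPattern(pattern),
        sample = sampleKey(ids) == pattern,
        position = positionKey(ids) == pattern,
        full = ids == pattern)
}

#' Read an exclusion list from a plain-text file
#'
#' One pattern per line; blank lines and lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return character vector of exclusion patterns.
#' @seealso [applyExclusions()] for the pattern grammar.
#' @export
readExclusionList <- function(path) {
    lines <- trimws(readLines(path, encoding = "UTF-8"))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    for (p in lines) .classifyPattern(p)
    lines
}

#' @describeIn applyExclusions Remove rows of a [SpectraSet] or [SensorTable]
#'   whose measurement ID matches any rule. Rules are ID fragments matched at
#'   three granularities: a full ID (`"N194_5"`) removes one measurement, a
#'   sample+position fragment (`"N144_Cn"`) removes all its repeats, and a
#'   sample fragment (`"T151"`) removes every position and repeat of that
#'   sample. Removing nothing (a rule matching zero rows) raises a warning,
#'   not an error; applying the same rules twice is a no-op. The removed IDs
#'   are recorded in `metadata(x)$excluded`.
#' @export
setMethod("applyExclusions", "MeasurementSet", function(x, rules, ...) {
    rules <- as.character(rules)
    drop <- rep(FALSE, length(x@ids))
    for (p in rules) {
        hit <- .patternMatches(p, x@ids)
        if (!any(hit))
            warning(sprintf("exclusion rule '%s' matched no measurements", p))
        drop <- drop | hit
    }
    removed <- x@ids[drop]
    out <- x[!drop]
    out@metadata$excluded <- c(x@metadata$excluded, removed)
    out
})
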