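#' @include accessors.R
NULL

#' Reduce full-resolution spectra to simulated LED sensor channels
#'
#' Each channel value is the weighted average of the spectrum with the LED's
#' emission curve as weights: for LED weights \eqn{w_k} interpolated onto the
#' spectrometer wavelength grid, the channel value of a spectrum \eqn{x} is
#' \eqn{\sum_k w_k x_k / \sum_k w_k}. Weights are zero outside the LED's
#' tabulated support (no extrapolation), so a flat spectrum maps to its own
#' constant value and each channel is bounded by the spectrum's range over
#' the LED support. Channels are ordered U1, U2, U3, U4 (then any further
#' labels) regardless of input order.
#'
#' @param spectra a [SpectraSet-class].
#' @param leds list of [LEDProfile-class] objects (e.g. from
#'   [generateLEDProfiles()]).
#' @return a [SensorTable-class] with one column per LED; row order and
#'   measurement IDs are carried over.
#' @examples
#' cfg <- TissueSimConfig(nPatients = 1, repeatsPerPosition = 1)
#' s <- simulateTissueSpectra(cfg)
#' simulateSensor(s, generateLEDProfiles(grid = wavelengths(s)))
#' @importFrom stats approx
#' @export
simulateSensor <- function(spectra, leds) {
    stopifnot(is(spectra, "SpectraSet"))
    if (is(leds, "LEDProfile"))
        leds <- list(leds)
    grid <- spectra@wavelengths
    X <- spectra@values
    labels <- vapply(leds, function(l) l@channel, character(1L))
    ord <- order(match(labels, c("U1", "U2", "U3", "U4")), labels)
    leds <- leds[ord]
    labels <- labels[ord]
    vals <- matrix(NA_real_, nrow(X), length(leds))
    for (j in seq_along(leds)) {
        l <- leds[[j]]
        if (any(l@intensity < 0))
            stop(sprintf("channel %s: negative LED weights", l@channel))
        w <- approx(l@wavelengths, l@intensity, xout = grid,
            yleft = 0, yright = 0)$y
        sw <- sum(w)
        if (sw <= 0)
            stop(sprintf(
                "channel %s: LED emission does not overlap the spectra's %s",
                l@channel, "wavelength range"))
        vals[, j] <- as.vector(X %*% (w / sw))
    }
    SensorTable(vals, labels, spectra@ids, metadata = spectra@metadata)
}
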