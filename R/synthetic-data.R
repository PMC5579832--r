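#' @include accessors.R
NULL

#' Configuration for the synthetic tissue-spectra generator
#'
#' See [TissueSimConfig-class] for the meaning of every parameter. Defaults
#' emulate the qualitative features of NIR diffuse-reflectance measurements of
#' kidney biopsies: reflectance well below 50% of the white standard, strong
#' additive baseline (offset) and multiplicative intensity (contrast)
#' variability between samples, water absorption dips near 970 and 1450 nm
#' and a lipid dip near 1210 nm, and tumor samples with higher offset, higher
#' contrast and higher between-measurement variance than normal tissue.
#'
#' @param nPatients patients; each contributes one tumor and one normal
#'   sample (default 7).
#' @param positionsPerSample measurement positions per sample (default 4; the
#'   first is the sample-center position `Cn`).
#' @param repeatsPerPosition repeats per position (default 5).
#' @param wavelengthGrid nm axis (default 512 points, 899.2--1721.4 nm).
#' @param bandCenters,bandWidths,bandDepths absorption-band centers (nm),
#'   Gaussian standard deviations (nm) and depths (reflectance-%); defaults
#'   970/1210/1450 nm, 40/60/80 nm, 6/5/14%.
#' @param baseOffset mean baseline reflectance of normal tissue in percent
#'   (default 30).
#' @param sampleOffsetSD,positionOffsetSD per-sample and per-position random
#'   baseline SDs in percent (defaults 4 and 1.5).
#' @param contrastJitterSD log-scale SD of the per-sample multiplicative
#'   contrast jitter (default 0.05).
#' @param classOffsetShift additive tumor-minus-normal offset in percent
#'   (default 5).
#' @param classContrastFactor multiplicative band-contrast gain of tumor
#'   spectra (default 1.3).
#' @param tumorVarianceInflation variance inflation (>= 1) of all tumor
#'   random effects (default 2).
#' @param noiseSD per-repeat measurement noise SD in percent (default 0.3).
#' @param seed integer seed (default 1).
#' @return a validated [TissueSimConfig-class] object.
#' @examples
#' cfg <- TissueSimConfig(nPatients = 2, repeatsPerPosition = 2)
#' simulateTissueSpectra(cfg)
#' @export
TissueSimConfig <- function(nPatients = 7L,
                            positionsPerSample = 4L,
                            repeatsPerPosition = 5L,
                            wavelengthGrid = seq(899.2, 1721.4,
                                length.out = 512L),
                            bandCenters = c(970, 1210, 1450),
                            bandWidths = c(40, 60, 80),
                            bandDepths = c(6, 5, 14),
                            baseOffset = 30,
                            sampleOffsetSD = 4,
                            positionOffsetSD = 1.5,
                            contrastJitterSD = 0.05,
                            classOffsetShift = 5,
                            classContrastFactor = 1.3,
                            tumorVarianceInflation = 2,
                            noiseSD = 0.3,
                            seed = 1L) {
    new("TissueSimConfig",
        nPatients = as.integer(nPatients),
        positionsPerSample = as.integer(positionsPerSample),
        repeatsPerPosition = as.integer(repeatsPerPosition),
        wavelengthGrid = as.numeric(wavelengthGrid),
        bandCenters = as.numeric(bandCenters),
        bandWidths = as.numeric(bandWidths),
        bandDepths = as.numeric(bandDepths),
        baseOffset = as.numeric(baseOffset),
        sampleOffsetSD = as.numeric(sampleOffsetSD),
        positionOffsetSD = as.numeric(positionOffsetSD),
        contrastJitterSD = as.numeric(contrastJitterSD),
        classOffsetShift = as.numeric(classOffsetShift),
        classContrastFactor = as.numeric(classContrastFactor),
        tumorVarianceInflation = as.numeric(tumorVarianceInflation),
        noiseSD = as.numeric(noiseSD),
        seed = as.integer(seed))
}

## Gaussian-sum absorption shape: negative dips on a zero baseline.
.bandShape <- function(grid, centers, widths, depths) {
    shape <- numeric(length(grid))
    for (j in seq_along(centers))
        shape <- shape - depths[j] *
            exp(-(grid - centers[j])^2 / (2 * widths[j]^2))
    shape
}

## position labels: sample center first, then grid cells B2, B3, C2, ...
.positionLabels <- function(n) {
    cells <- as.vector(outer(2:9, LETTERS[2:9],
        function(i, l) paste0(l, i)))
    c("Cn", cells)[seq_len(n)]
}

#' Generate LED emission profiles
#'
#' Models each LED as a Gaussian emission curve of configurable full width at
#' half maximum, evaluated on a wavelength grid and normalized to peak
#' intensity 1. Channel labels follow the four-LED sensor mapping
#' (0.94 um -> U4, 1.17 um -> U3, 1.30 um -> U1, 1.44 um -> U2); peaks
#' outside that set are labelled `U1`, `U2`, ... in input order.
#'
#' @param peaks emission maxima in micrometres
#'   (default `c(0.94, 1.17, 1.30, 1.44)`).
#' @param fwhm full widths at half maximum in nm, recycled over peaks
#'   (default 60).
#' @param grid wavelength grid in nm on which to tabulate the profiles.
#' @return a named list of [LEDProfile-class] objects, one per peak, in input
#'   order.
#' @examples
#' leds <- generateLEDProfiles(grid = seq(900, 1700, by = 1))
#' vapply(leds, channels, character(1))
#' @export
generateLEDProfiles <- function(peaks = c(0.94, 1.17, 1.30, 1.44),
                                fwhm = 60,
                                grid = seq(899.2, 1721.4, length.out = 512L)) {
    if (any(fwhm <= 0))
        stop("all FWHM values must be positive")
    fwhm <- rep_len(fwhm, length(peaks))
    canonical <- c("0.94" = "U4", "1.17" = "U3", "1.3" = "U1", "1.44" = "U2")
    out <- vector("list", length(peaks))
    for (i in seq_along(peaks)) {
        peakNM <- peaks[i] * 1000
        if (peakNM < min(grid) || peakNM > max(grid))
            stop(sprintf("LED peak %.3f um lies outside the wavelength grid",
                peaks[i]))
        key <- as.character(peaks[i])
        label <- if (key %in% names(canonical)) canonical[[key]] else
            paste0("U", i)
        sd <- fwhm[i] / (2 * sqrt(2 * log(2)))
        intensity <- exp(-(grid - peakNM)^2 / (2 * sd^2))
        out[[i]] <- LEDProfile(label, peaks[i], grid, intensity)
    }
    names(out) <- vapply(out, function(l) l@channel, character(1L))
    out
}

#' Simulate grouped tumor/normal NIR reflectance spectra
#'
#' Generates one tumor (`T`) and one normal (`N`) sample per patient, with
#' `positionsPerSample` measurement positions per sample and
#' `repeatsPerPosition` repeated measurements per position. Each measurement
#' is
#' \deqn{r(\lambda) = o_s + o_p + c_s\, g(\lambda) + \varepsilon(\lambda),}
#' where \eqn{g(\lambda)} is a sum of negative Gaussian absorption bands,
#' \eqn{o_s} a per-sample baseline offset (tumor samples shifted upward by
#' `classOffsetShift`), \eqn{o_p} a per-position offset, \eqn{c_s} a
#' per-sample contrast (tumor scaled by `classContrastFactor`), and
#' \eqn{\varepsilon} i.i.d. noise. Tumor random effects and noise have their
#' standard deviations inflated by `sqrt(tumorVarianceInflation)`. Values are
#' clipped to the physically plausible reflectance range (0, 50] percent of
#' the white standard. The same seed always yields a bit-identical dataset.
#'
#' @param config a [TissueSimConfig-class] object.
#' @return a [SpectraSet-class]; rows are ordered patient, class (N then T),
#'   position, repeat, with identifiers such as `"T101_Cn_2"`.
#' @export
simulateTissueSpectra <- function(config) {
    validObject(config)
    withLocalSeed(config@seed, {
        grid <- config@wavelengthGrid
        shape <- .bandShape(grid, config@bandCenters, config@bandWidths,
            config@bandDepths)
        posLabels <- .positionLabels(config@positionsPerSample)
        patients <- 100L + seq_len(config@nPatients)
        nRows <- config@nPatients * 2L * config@positionsPerSample *
            config@repeatsPerPosition
        values <- matrix(NA_real_, nRows, length(grid))
        ids <- character(nRows)
        row <- 0L
        for (p in patients) {
            for (cls in c("N", "T")) {
                isT <- cls == "T"
                infl <- if (isT) sqrt(config@tumorVarianceInflation) else 1
                offsetS <- config@baseOffset +
                    (if (isT) config@classOffsetShift else 0) +
                    stats::rnorm(1L, 0, config@sampleOffsetSD * infl)
                contrastS <- (if (isT) config@classContrastFactor else 1) *
                    exp(stats::rnorm(1L, 0, config@contrastJitterSD * infl))
                for (pos in posLabels) {
                    offsetP <- stats::rnorm(1L, 0,
                        config@positionOffsetSD * infl)
                    for (rep in seq_len(config@repeatsPerPosition)) {
                        noise <- if (config@noiseSD > 0)
                            stats::rnorm(length(grid), 0,
                                config@noiseSD * infl)
                        else numeric(length(grid))
                        row <- row + 1L
                        values[row, ] <- offsetS + offsetP +
                            contrastS * shape + noise
                        ids[row] <- sprintf("%s%d_%s_%d", cls, p, pos, rep)
                    }
                }
            }
        }
        if (all(values <= 0))
            stop("configuration yields non-positive reflectance everywhere; ",
                "increase 'baseOffset' or reduce band depths")
        values <- pmin(values, 50)
        values <- pmax(values, 0.001)
        SpectraSet(values, grid, ids,
            metadata = list(simConfig = config))
    })
}
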