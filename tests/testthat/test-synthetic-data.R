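test_that("LED set carries the four-channel peak mapping", {
    grid <- seq(900, 1700, by = 1)
    leds <- generateLEDProfiles(c(0.94, 1.17, 1.30, 1.44), grid = grid)
    expect_identical(names(leds), c("U4", "U3", "U1", "U2"))
    argmax <- vapply(leds, function(l)
        l@wavelengths[which.max(l@intensity)], numeric(1))
    expect_equal(unname(argmax), c(940, 1170, 1300, 1440))
    for (l in leds) expect_equal(max(l@intensity), 1.0)
})

test_that("LED Gaussians hit half maximum at peak +/- FWHM/2", {
    grid <- seq(1000, 1600, by = 10)   # contains 1270, 1300, 1330
    led <- generateLEDProfiles(1.30, fwhm = 60, grid = grid)[[1]]
    at <- function(nm) led@intensity[match(nm, led@wavelengths)]
    expect_equal(at(1300), 1.0, tolerance = 1e-12)
    expect_equal(at(1270), 0.5, tolerance = 1e-6)
    expect_equal(at(1330), 0.5, tolerance = 1e-6)
})

test_that("a peak outside the wavelength grid is refused by name", {
    expect_error(generateLEDProfiles(0.50, grid = seq(900, 1700, 10)),
        "0.500 um")
})

test_that("group structure and determinism of the generator", {
    cfg <- TissueSimConfig(nPatients = 3, positionsPerSample = 2,
        repeatsPerPosition = 4, seed = 11)
    s1 <- simulateTissueSpectra(cfg)
    expect_equal(dim(s1)[1], 3L * 2L * 2L * 4L)
    s2 <- simulateTissueSpectra(cfg)
    expect_identical(intensityMatrix(s1), intensityMatrix(s2))
    expect_identical(measurementIDs(s1), measurementIDs(s2))
    # metadata encodes the nesting
    info <- parseMeasurementID(measurementIDs(s1))
    expect_setequal(unique(info$position), c("Cn", "B2"))
    expect_equal(sort(unique(info$repeatIndex)), 1:4)
})

test_that("without noise, repeats of one position are identical rows", {
    cfg <- TissueSimConfig(nPatients = 1, positionsPerSample = 1,
        repeatsPerPosition = 3, noiseSD = 0, tumorVarianceInflation = 1,
        seed = 2)
    X <- intensityMatrix(simulateTissueSpectra(cfg))
    expect_identical(X[1, ], X[2, ])
    expect_identical(X[2, ], X[3, ])
})

test_that("reflectance stays in (0, 50] percent of the standard", {
    s <- simulateTissueSpectra(TissueSimConfig(seed = 9))
    X <- intensityMatrix(s)
    expect_true(all(X > 0))
    expect_true(all(X <= 50))
    at900 <- X[, which.min(abs(wavelengths(s) - 900))]
    expect_true(all(at900 > 0 & at900 <= 50))
})

test_that("the configured tumor offset shift is recovered from 1000 rows", {
    cfg <- TissueSimConfig(nPatients = 25, seed = 42)   # 1000 rows
    s <- simulateTissueSpectra(cfg)
    X <- intensityMatrix(s)
    wl <- wavelengths(s)
    # per-row baseline estimated in the band-free region beyond 1620 nm
    off <- rowMeans(X[, wl > 1620])
    sk <- sampleKeyForTest(measurementIDs(s))
    sm <- tapply(off, sk, mean)
    isT <- startsWith(names(sm), "T")
    d <- mean(sm[isT]) - mean(sm[!isT])
    se <- sqrt(var(sm[isT]) / sum(isT) + var(sm[!isT]) / sum(!isT))
    expect_lt(abs(d - 5), 3 * se)
})

test_that("a configuration with no positive reflectance is refused", {
    expect_error(simulateTissueSpectra(TissueSimConfig(nPatients = 1,
        baseOffset = -100, sampleOffsetSD = 0.01, positionOffsetSD = 0.01,
        noiseSD = 0, seed = 1)), "non-positive reflectance")
})

test_that("larger class offset shift does not reduce RSV accuracy", {
    acc <- sapply(1:10, function(sd) {
        sapply(c(0.5, 5), function(shift) {
            sen <- makeSyntheticSensor(seed = sd, nPatients = 3,
                positionsPerSample = 2, repeatsPerPosition = 3,
                classOffsetShift = shift)
            suppressWarnings(randomSubsetValidation(sen,
                iterations = 100, seed = sd))@ac
        })
    })
    expect_gte(mean(acc[2, ]), mean(acc[1, ]))
})

test_that("invalid configurations fail validity", {
    expect_error(TissueSimConfig(wavelengthGrid = c(1000, 900)),
        "strictly increasing")
    expect_error(TissueSimConfig(bandWidths = c(-1, 60, 80)), "positive")
    expect_error(TissueSimConfig(tumorVarianceInflation = 0.5), "at least 1")
    expect_error(TissueSimConfig(noiseSD = -1), "non-negative")
})
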