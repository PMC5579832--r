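test_that("spectra CSV round-trip is lossless within float formatting", {
    set.seed(3)
    s <- SpectraSet(matrix(rnorm(15, 30), 3, 5),
        c(900, 1000.5, 1100, 1200.25, 1300), c("T1_1", "T1_2", "N1_1"))
    f <- withr::local_tempfile(fileext = ".csv")
    writeSpectra(s, f)
    s2 <- readSpectra(f)
    expect_equal(intensityMatrix(s2), intensityMatrix(s), tolerance = 1e-9)
    expect_identical(measurementIDs(s2), measurementIDs(s))
    expect_equal(wavelengths(s2), wavelengths(s))
})

test_that("defective CSV inputs are rejected", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("id,900,1000", "T1_1,1,2", "T1_1,3,4"), f)
    expect_error(readSpectra(f), "duplicate")
    writeLines(c("id,900,1000", "T1_1,1,two"), f)
    expect_error(readSpectra(f), "non-numeric")
    writeLines(c("id,apple,1000", "T1_1,1,2"), f)
    expect_error(readSpectra(f), "wavelength headers")
})

test_that("a 41 x 512 matrix file yields 41 measurements at 512 wavelengths", {
    set.seed(4)
    ids <- sprintf("%s19%d_%d", rep(c("T", "N"), c(21, 20)),
        rep(1:7, length.out = 41), 1:41)
    s <- SpectraSet(matrix(runif(41 * 512, 5, 45), 41),
        seq(899.2, 1721.4, length.out = 512), ids)
    f <- withr::local_tempfile(fileext = ".csv")
    writeSpectra(s, f)
    expect_equal(dim(readSpectra(f)), c(41L, 512L))
})

test_that("LED profile CSV round-trips channels, peaks and curves", {
    leds <- generateLEDProfiles(grid = seq(900, 1700, by = 2))
    f <- withr::local_tempfile(fileext = ".csv")
    writeLEDProfiles(leds, f)
    back <- readLEDProfiles(f)
    expect_identical(names(back), names(leds))
    for (ch in names(leds)) {
        expect_equal(back[[ch]]@peak, leds[[ch]]@peak)
        expect_equal(back[[ch]]@intensity, leds[[ch]]@intensity,
            tolerance = 1e-6)
    }
})

test_that("exclusion rules remove sample, position and single-ID groups", {
    tbl <- makeSeriesBLikeTable()
    expect_equal(nrow(tbl)[1], 170L)
    out <- applyExclusions(tbl, c("T151", "N144_Cn", "T144_Cn"))
    expect_equal(dim(out)[1], 140L)
    expect_length(metadata(out)$excluded, 30L)
    expect_false(any(startsWith(measurementIDs(out), "T151")))
    expect_false(any(grepl("^N144_Cn_", measurementIDs(out))))
})

test_that("exclusions are idempotent and the empty list is the identity", {
    tbl <- makeSeriesBLikeTable()
    once <- applyExclusions(tbl, "T151")
    twice <- suppressWarnings(applyExclusions(once, "T151"))
    expect_identical(intensityMatrix(twice), intensityMatrix(once))
    same <- applyExclusions(tbl, character())
    expect_identical(intensityMatrix(same), intensityMatrix(tbl))
})

test_that("a full-ID rule removes exactly one measurement; zero matches warn", {
    set.seed(5)
    ids <- c("N194_1", "N194_2", "N194_5", "T194_1")
    tbl <- SensorTable(matrix(rnorm(16), 4), paste0("U", 1:4), ids)
    out <- applyExclusions(tbl, "N194_5")
    expect_equal(dim(out)[1], 3L)
    expect_false("N194_5" %in% measurementIDs(out))
    expect_warning(applyExclusions(tbl, "T999"), "matched no measurements")
})

test_that("exclusion lists read from plain text, skipping comments", {
    f <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("# documented exclusions", "T151", "", "N144_Cn"), f)
    expect_identical(readExclusionList(f), c("T151", "N144_Cn"))
    writeLines("not-an-id", f)
    expect_error(readExclusionList(f), "not a valid")
})
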