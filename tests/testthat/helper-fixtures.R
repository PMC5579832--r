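# Shared fixtures, all built in code.

# Two well-separated multivariate clusters (0 = normal-like, 1 = tumor-like).
makeSeparableData <- function(nPerClass = 10L, p = 4L, gap = 6, sd = 0.5,
                              seed = 1L) {
    set.seed(seed)
    X <- rbind(matrix(rnorm(nPerClass * p, 0, sd), nPerClass),
               matrix(rnorm(nPerClass * p, gap, sd), nPerClass))
    list(X = X, y = rep(c(0, 1), each = nPerClass))
}

# Sensor table shaped like the second measurement series: grouped IDs with
# grid positions, engineered so that sample T151 has 20 rows and positions
# N144_Cn / T144_Cn have 5 rows each, 170 rows in total.
makeSeriesBLikeTable <- function(seed = 1L) {
    set.seed(seed)
    ids <- character()
    addRows <- function(cls, patient, positions, repeats) {
        for (pos in positions)
            for (r in seq_len(repeats))
                ids <<- c(ids, sprintf("%s%d_%s_%d", cls, patient, pos, r))
    }
    addRows("T", 151, c("B2", "B3", "C2", "C3"), 5L)          # 20 rows
    addRows("N", 151, c("B2", "C2"), 5L)                      # 10
    addRows("N", 144, c("Cn", "B2", "C2"), 5L)                # 15 (Cn = 5)
    addRows("T", 144, c("Cn", "B2", "C2", "D2"), 5L)          # 20 (Cn = 5)
    addRows("N", 149, c("Cn", "B2", "C2", "D2"), 5L)          # 20
    addRows("T", 149, c("Cn", "B2", "C2"), 5L)                # 15
    addRows("N", 160, c("Cn", "B2", "C2", "D2", "D3"), 5L)    # 25
    addRows("T", 160, c("Cn", "B2", "C2", "D2", "E2"), 5L)    # 25
    addRows("N", 162, c("Cn", "B2"), 5L)                      # 10
    addRows("T", 162, c("Cn", "B2"), 5L)                      # 10
    stopifnot(length(ids) == 170L)
    SensorTable(matrix(rnorm(170 * 4), 170), c("U1", "U2", "U3", "U4"), ids)
}

# Sample key ("T151") re-derived independently of package internals.
sampleKeyForTest <- function(ids) sub("^([TN][0-9]+).*$", "\\1", ids)

# Default-condition synthetic sensor table (strong class separation).
makeSyntheticSensor <- function(seed = 1L, ...) {
    cfg <- TissueSimConfig(seed = seed, ...)
    spectra <- simulateTissueSpectra(cfg)
    simulateSensor(spectra, generateLEDProfiles(grid = wavelengths(spectra)))
}
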