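Package: nirled
Title: LED-Based Near-Infrared Sensor Simulation and PLS-DA Tissue Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for developing and validating LED-based near-infrared (NIR)
    diffuse-reflectance sensors for binary tissue discrimination, motivated by
    kidney tumor diagnostics. Provides a synthetic generator for grouped
    tumor/normal reflectance spectra, parsing of the measurement-identifier
    convention (tissue class, patient, position, repeat), spectral
    preprocessing (mean centering, Savitzky-Golay second derivatives, standard
    normal variate), reduction of full-resolution spectra to a few LED
    channels by emission-weighted averaging, PLS-DA discrimination via NIPALS
    PLS1 with a configurable decision threshold, the discriminant Q-squared
    (DQ2) statistic, and a validation battery: leave-one-out and segmented
    cross-validation, random-subset validation with cumulative confusion
    counts, latent-variable selection, and a label-permutation test scored by
    the mean number of misclassified measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'metrics.R'
    'cross-validation.R'
    'spectra-io.R'
    'exclusions.R'
    'measurement-id.R'
    'models.R'
    'random-subset.R'
    'permutation-test.R'
    'pipeline.R'
    'preprocessing.R'
    'sensor-sim.R'
    'show-methods.R'
    'synthetic-data.R'
    'utils.R'
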