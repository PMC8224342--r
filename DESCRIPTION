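Package: sowtherm
Title: Comparison of Thermal Comfort Indices for Heat Stress in Sows
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluates and compares twelve livestock thermal-comfort indices
    (eight temperature-humidity index variants, the black globe-humidity
    index, effective temperature, the equivalent temperature index of sows,
    and moist-air enthalpy) for assessing heat stress in sow housing.
    Provides the empirical psychrometric conversions the index formulas
    consume (dew-point, wet-bulb and black-globe temperature), heat-stress
    threshold classification, an equivalent-temperature-change analysis that
    holds an index constant while relative humidity changes, air-velocity
    response curves with crossing detection against a winter reference,
    iso-index line tracing on the psychrometric plane, a seeded one-dimensional
    zonal energy-balance surrogate of a ten-sow barn, and a correlation and
    ranking stage relating each index to per-sow convective heat dissipation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
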