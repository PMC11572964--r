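Package: canopycooler
Title: Scaling Analysis of Urban Tree Canopy Cooling Efficiency
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Multi-scale analysis of the cooling efficiency (CE) of urban
    tree canopy: aggregates paired land-surface-temperature and canopy
    rasters onto ladders of square analytical units, estimates CE at each
    unit size as the absolute OLS slope of unit-mean LST on percent canopy
    cover, fits the CE-versus-size relationship to a power law with a
    quadratic fallback, extrapolates CE to the whole-city scale, inverts it
    into canopy-increase goals for target temperature reductions, and
    relates per-date scaling exponents to weather covariates including
    vapor pressure deficit. Includes seeded synthetic generators for unit
    tables and raster pairs so the full pipeline is testable without
    satellite or aerial imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
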