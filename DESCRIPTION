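Package: sithv2
Title: SiTHv2 Ecohydrological Simulator: Evapotranspiration Partitioning and
    Three-Layer Soil Moisture
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Daily simulation of terrestrial evapotranspiration (ET) and its
    components (plant transpiration, bare-soil evaporation, canopy interception
    evaporation) together with three-layer soil moisture and a dynamic
    groundwater table, following the SiTHv2 model of the
    groundwater-soil-plant-atmosphere continuum. Potential fluxes use the
    Priestley-Taylor equation; actual fluxes apply multiplicative constraints
    for canopy wetness, soil moisture, temperature and vegetation water content
    (via microwave vegetation optical depth); root water uptake follows a
    linear dose-response depth profile split between unsaturated and saturated
    zones. Includes a seed-controlled synthetic forcing generator for three
    climate regimes, point and grid drivers with spin-up and temporal
    aggregation, packed-integer NetCDF product output with the published
    filename scheme, bilinear regridding and spline gap-filling of forcing, and
    validation metrics (Pearson r, RMSE, Nash-Sutcliffe efficiency,
    water-balance ET, Mann-Kendall trend tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    parallel
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
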