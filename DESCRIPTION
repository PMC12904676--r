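Package: careatlas
Title: Geographic Accessibility Analysis for Health-Care Facilities
Version: 0.1.0
Authors@R:
    person("careatlas", "developers", email = "careatlas@example.org",
           role = c("aut", "cre"))
Description: Least-cost travel-time surfaces from health facility registries
    over a friction raster, access population coverage (APC) at configurable
    time thresholds, facility density per population, urban/rural and zonal
    stratification, and facility-network scenario comparison. Includes a
    seeded synthetic-world generator (friction, population, zones, urban
    mask, tiered facility registries) so the full pipeline is testable
    without external geodata, plus a minimal single-band GeoTIFF reader and
    writer so no system GIS libraries are required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
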