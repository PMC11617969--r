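Package: parkzoning
Title: Risk-Value Zoning of National Parks from Categorical Land-Use Rasters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for "risk-value" zoning of protected areas that follow China's
    "one park, two zones" model. From a categorical land-use raster and a
    core/general zone mask, the package tessellates the park into square
    assessment units, computes landscape fragmentation, isolation and dominance
    metrics per land-use class, combines them with ecological vulnerability
    ranks into a per-unit Ecological Risk Index (ERI) over the core protected
    area, and values ecosystem services per unit over the general control area
    with the equivalent-factor method (ESV). Unit values are interpolated to
    continuous surfaces by ordinary kriging, graded into five classes with
    exact Fisher-Jenks natural breaks, and synthesised into a four-zone
    CHR/CLR/GHE/GLE map with area and service-value reports. A neutral
    landscape generator (modified random clusters) produces synthetic rasters
    and park masks with controllable fragmentation so the whole pipeline is
    testable without geodata downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
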