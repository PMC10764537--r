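Package: mfac
Title: Modified Flow Accumulation Capacity Modelling for Blanket Bogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Terrain-based surface-wetness modelling for blanket peatlands.
    Implements the Modified Flow Accumulation Capacity (MFAC) model, a
    topographic wetness index variant for rain-fed peatlands: depression
    filling, D8 flow routing and accumulation on bare-earth digital terrain
    models, flowline extraction and natural-neighbour (Sibson) interpolation
    of contributing area, focal-mean terrain smoothing and slope in m/km,
    and a climatic correction factor scaling effective rainfall between
    sites. Companion tools compute water-table exceedance statistics (D90,
    D10, median, D1 minus D99) from hourly logger series, summarise daily
    meteorological forcing, derive hydraulic gradients from well nests, and
    fit the ordinary least squares regressions of water-table statistics on
    log10(MFAC) with ANOVA significance tests and prediction intervals.
    Synthetic terrain, meteorology and water-table generators plus bundled
    monitoring summary tables from four Irish blanket bogs allow the whole
    pipeline to run self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
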