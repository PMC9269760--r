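Package: rseikit
Title: Remote Sensing Ecological Index Workflows for Coastal Saline-Alkali
    Vegetation Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds the Remote Sensing Ecological Index (RSEI) for small
    coastal reserves from six indicator rasters: aerosol optical depth
    retrieved over dense dark vegetation by lookup-table inversion, soil
    salinity inverted from multispectral reflectance by multiple linear
    regression or a single-hidden-layer neural network, greenness (NDVI),
    wetness (tasseled cap), dryness (bare soil index) and heat (single
    channel land surface temperature). Indicators are percentile-normalized,
    composed by spatial principal component analysis, graded into five
    ecological classes, and compared across dates by image differencing.
    A synthetic-scene generator with known aerosol, salinity and temperature
    truth fields makes every stage testable without satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
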