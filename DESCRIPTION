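Package: marshAGB
Title: Marsh Aboveground Biomass Estimation and Climate Attribution from NDVI Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates a power-law model linking annual maximum NDVI to marsh
    aboveground biomass (AGB) carbon density from field quadrat samples, applies
    it over a stable marsh mask to a multi-year NDVI raster series, and quantifies
    per-pixel and regional AGB trends together with monthly and annual climate
    correlations based on ordinary kriging of station records. Includes a
    synthetic-scene generator with known ground truth (marsh masks, seasonal NDVI
    stacks, station climate, quadrat samples) so every pipeline stage can be
    exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
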