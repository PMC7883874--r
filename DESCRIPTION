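Package: fusionfield
Title: Sensor Fusion of Canopy Height and Multispectral Data for
    Legume-Grass Biomass and Nitrogen Fixation Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates fresh matter, dry matter and symbiotic nitrogen
    fixation of legume-grass mixtures by fusing structural information from
    terrestrial laser scans (crop surface height rasters and their
    distributional metrics) with spectral information from four-band
    multispectral imagery (band means, vegetation indices) and gray-level
    co-occurrence texture features computed from both sources. Provides a
    synthetic field-experiment generator (point clouds, reflectance rasters,
    plot polygons, ground truth) with the statistical structure the analysis
    assumes, the difference-method nitrogen fixation bookkeeping, a
    three-step random-forest variable selection, and repeated stratified
    split validation with range-normalised error metrics and nonparametric
    year-effect tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    ranger,
    rpart,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
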