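Package: vertsc
Title: Vertical Structural Complexity of Plant Communities: Metrics,
    Drivers and Spatial Upscaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantifies the vertical structural complexity (VSC) of plant
    communities from plot survey tables as maximum plant height, the
    coefficient of variation of plant height, and the Shannon evenness of
    height classes weighted by basal area (woody plots) or species
    importance values (grassland plots). Attributes spatial variation in
    VSC to resource versus non-resource environmental drivers through
    Pearson screening, stepwise AIC regression, LMG relative-importance
    decomposition, variance inflation factors, bootstrap size-matching and
    Moran's I residual diagnostics, and upscales plot-level VSC to gridded
    maps with random forests and ordinary kriging of sparse predictor
    layers. Ships a synthetic-data generator emulating a high-plateau
    survey across five vegetation types so the full pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    geosphere,
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    ape,
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
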