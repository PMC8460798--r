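Package: emergephen
Title: Thermal-Time Models of Autumn Weed Seedling Emergence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Degree-day driven phenology modelling of annual bluegrass
    (Poa annua) seedling emergence in managed turfgrass. Accumulates
    cooling degree days from the summer solstice, builds yearly-cumulative
    and early-season emergence curves from dated seedling counts, fits
    Gompertz and saturating-exponential (ruminal degradation) emergence
    models by multi-start nonlinear least squares, inverts fitted curves
    to thermal-time benchmarks (e.g. 50% and 75% emergence), screens
    environmental predictors by Pearson correlation, detects peak-emergence
    windows with concurrent edaphic summaries, and simulates weather and
    emergence data with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
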