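Package: canopyair
Title: Airflow Velocity Attenuation Modelling in Fruit-Tree Canopies
Version: 0.1.0
Authors@R:
    person("canopyair", "developers", email = "canopyair@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling the attenuation of air-assisted spray jets
    inside fruit-tree canopies. Estimates the exponential velocity
    attenuation factor k from canopy drag measurements by inverting a
    closed-form aerodynamic resistance equation, predicts in-canopy
    velocity profiles (single-layer and two-layer), applies a dynamic
    windward-area correction for the outer canopy, estimates leaf windward
    area from white-background projection images, scores model-measurement
    agreement, and generates synthetic measurement campaigns for testing.
    Includes a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
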