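Package: mazepoint
Title: Pointing-Error Analysis and Cognitive-Map Distortion Modeling for
    Route Mazes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing directional pointing judgments collected
    in hedge-corridor mazes. Covers route-based maze geometry and 2.5-D
    visibility modelling (line of sight, isovists, visible/non-visible
    trial classification), von Mises mixture modelling with BIC-based
    bimodality detection for circular pointing data, construction of
    distorted "alternative" maze representations through composable route
    edits, per-participant representation-fit comparison, cohort scoring
    and filtering rules (Raw TLX, sense-of-direction median split,
    visible-error outlier exclusion), and a synthetic cohort generator
    with the statistical structure the analysis assumes.
License: MIT + file LICENSE
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
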