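Package: elevrange
Title: Elevational Range-Size Gradients, Mid-Domain Null Models and Their Drivers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing Rapoport's rule along elevational gradients in
    plot-based vascular-plant surveys. Estimates per-species elevational ranges
    from a plot-by-species occurrence matrix, computes Stevens' per-plot mean
    range-size profiles for life-form and biogeographical-affinity groups, runs
    a Monte-Carlo mid-domain-effect null model with empirical range sizes
    reshuffled without replacement, builds per-plot environmental predictor
    tables (station climate summaries interpolated by one-dimensional ordinary
    kriging, inverse-distance-weighted human population, present-minus-LGM
    climate deltas), and relates range size to predictors with standardized
    ordinary least squares, simultaneous autoregressive error models, and
    repeated random-forest permutation importance. A seeded synthetic-community
    generator with a tunable planted range-size slope makes every stage
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
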