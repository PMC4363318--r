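Package: nichekit
Title: Trait-Based Niche Metrics for Monoculture-Mixture Biodiversity Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing intraspecific functional-trait variation in
    monoculture versus mixture biodiversity experiments. Provides shoot-level
    trait table input/output and validation, a synthetic-data generator
    emulating a blocked grassland design, a preprocessing chain (log
    transforms, block correction, z-standardization), distance-based niche
    statistics (niche density, width, separation, shift, and community trait
    space filling and range), phenotypic-integration summaries based on
    counts of significant pairwise trait correlations, and the accompanying
    inference chain: mixed-effects likelihood-ratio tests for trait
    responses, reaction norms, tests on niche metrics with a permutation
    alternative, proportional diversity effects on shoot biomass, and
    mixed-model comparison of per-shoot niche predictors for those diversity
    effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    emmeans,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
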