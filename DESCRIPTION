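Package: vegniche
Title: Gaussian-Niche Ground-Vegetation Community Composition Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates the composition of forest understory plant
    communities from monthly soil and light drivers. Each species carries
    Gaussian fundamental-niche response curves for soil-solution pH,
    nitrogen, soil moisture and light, a hard temperature window, a
    rooting depth that selects which soil layers it experiences, and a
    shading height through which taller plants attenuate the light
    available to shorter ones. Per-species suitabilities are turned into
    normalized relative surface covers by proportional competition. The
    package also provides a greedy class-rank calibration that adjusts
    niche optima until every species' simulated cover is within five
    percentage points of observation, a model-evaluation metric suite
    (normalized average error, normalized root-mean-square error,
    zero-intercept 1:1 regression, Czekanowski similarity index), and a
    synthetic monthly driver generator with seasonal cycle, long-term
    trend and noise for testing the model without a biogeochemical
    simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
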