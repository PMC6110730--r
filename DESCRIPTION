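Package: physprr
Title: Post-Reproductive Lifespans in Toothed Whales from Ovarian Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects post-reproductive lifespans in toothed whales from
    age-specific ovarian corpora counts. Fits linear and quadratic
    age-corpora models with AIC selection, derives age-specific ovarian
    activity and the relative rate of reproductive senescence, builds
    growth-adjusted life tables from cross-sectional age samples by
    reverse variable-width cohort binning, computes physiological
    post-reproductive representation (Phys-PrR) with a Monte-Carlo
    significance test, and reconstructs the presence or absence of
    post-reproductive lifespans on a phylogeny under a two-state
    equal-rates Markov model. Includes an individual-based generator of
    synthetic corpora datasets with known senescence structure for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
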