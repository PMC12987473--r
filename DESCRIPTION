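Package: melonopt
Title: Entropy-Weight TOPSIS and Surrogate-Assisted Multi-Objective
    Optimization of Melon Cultivation Configurations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decision-analysis chain for choosing a cultivation
    configuration (plant spacing by pruning-fruit-retention method) for
    netted melon field trials. Implements entropy-weight TOPSIS scoring of
    treatment-by-indicator fruit-quality tables, inclusive phenology
    duration arithmetic over stage-date tables, a small feed-forward
    neural surrogate mapping (spacing, pruning) to (growth duration,
    yield, comprehensive quality), elitist NSGA-II search over the
    discrete feasible design grid with an exhaustive Pareto oracle, and
    equal-weight weighted-sum selection of a single recommended
    configuration. Includes a synthetic two-factor trial generator with
    planted optima for end-to-end recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse
Config/testthat/edition: 3
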