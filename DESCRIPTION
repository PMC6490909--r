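Package: nutribbn
Title: Bayesian Belief Network Assessment of Nutrient-Regulation Ecosystem Services
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete Bayesian belief network (BBN) toolkit for mapping the
    potential, demand and budget of the nutrient-regulation (nitrogen)
    ecosystem service across landscape grids. Provides an exact-inference
    engine (variable elimination over conditional probability tables), a
    14-node nutrient-regulation model with its discretization and
    classification rules, maximum-likelihood CPT learning with optional
    pseudocounts, posterior sensitivity analysis under proportional
    covariation, mutual-information arc strengths, k-fold cross-validation,
    a seeded synthetic landscape-grid generator, and a configurable
    end-to-end pipeline producing per-cell service classifications.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
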