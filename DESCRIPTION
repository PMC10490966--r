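Package: lulcesv
Title: Land-Use/Land-Cover Change Detection and Ecosystem Service Valuation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-temporal land-use/land-cover (LULC) analysis and
    benefit-value-transfer ecosystem service valuation. Provides Gaussian
    maximum-likelihood supervised classification from training signatures,
    NDVI computation with fixed-threshold vegetation-density classes,
    confusion-matrix accuracy assessment (overall accuracy, producer's and
    user's accuracy, Cohen's kappa), post-classification change detection
    with annualized change rates and full transition matrices (gains,
    losses, net change, net-change-to-persistence), per-class and
    per-function ecosystem service valuation from value-coefficient tables,
    and coefficient-of-sensitivity elasticity analysis under proportional
    coefficient perturbations. A synthetic-scene generator produces
    multi-epoch class maps under a known Markov transition model with
    per-class Gaussian band reflectances, so the whole pipeline is testable
    without satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
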