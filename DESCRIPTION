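Package: samtox
Title: Stress Addition Modelling of Combined Toxicant and Environmental Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the joint mortality of a toxicant and an independent
    environmental stressor with the Stress Addition Model (SAM): individual
    stress tolerance is modelled as a beta-distributed general stress capacity,
    each stressor's mortality is transferred to a general stress level through
    the beta quantile, stress levels add, and the beta distribution function of
    the sum gives the combined mortality. Includes five-parameter log-logistic
    concentration-response fitting with Williams-type monotonisation and
    log-scale interpolation smoothing, lethal-concentration (LCx) estimation and
    sensitivity-shift factors, the classical mixture baselines of effect
    addition (Bliss) and an adapted concentration addition, a meta-analysis
    layer (curve normalisation and averaging, shape-parameter calibration,
    goodness of fit, overall shift predictions), and a synthetic study-pair
    generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
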