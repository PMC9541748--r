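Package: ricurve
Title: Fourier-Based Reproductive Investment Curves for Longitudinal
    Breeding Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decomposes individual reproductive time series (e.g. yearly
    clutch sizes) into sinusoidal reproductive investment curves (RICs) via
    the discrete Fourier transform, classifies individuals by the temporal
    scale and peak-to-trough amplitude of their dominant curve (short-term
    inter-annual alternation versus long-term, senescence-like waves), and
    compares populations with AICc-based multimodel inference: all-subsets
    model sets over population, sex and individual quality with a
    birth-year random intercept, Akaike weights, weighted model averaging
    within two AICc units, and estimated marginal means on the response
    scale. Includes filtering and mean-centring of long-format breeding
    records, an individual-based life-history simulator with known ground
    truth for recovery testing, and an end-to-end pipeline with a hashed
    run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    jsonlite,
    lme4,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
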