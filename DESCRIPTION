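Package: nirsfit
Title: Optimal Hemodynamic Response Estimation for fNIRS Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the hemodynamic response in functional near-infrared
    spectroscopy (fNIRS) channel recordings by fitting a twelve-parameter
    signal model -- a double-gamma canonical hemodynamic response function
    convolved with a boxcar task paradigm, plus cardiac, respiratory and
    Mayer-wave sinusoids and a baseline -- with a box-constrained
    Nelder-Mead simplex optimizer written for this problem. Includes
    modified Beer-Lambert law conversion of dual-wavelength optical-density
    changes to oxy-/deoxy-hemoglobin concentration changes, per-channel
    t-statistic activation maps on the optode grid, and a synthetic-data
    generator with the fifteen reference parameter sets used for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
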