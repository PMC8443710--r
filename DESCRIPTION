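Package: gamye
Title: Hierarchical Bayesian GAMYE Trend Models for Route-Level Count Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Bayesian hierarchical Generalized Additive Models with Year
    Effects (GAMYE) to route-level count-survey data such as the North American
    Breeding Bird Survey: overdispersed Poisson counts with stratum-level
    B-spline smooths shrunk toward a continental mean smooth, annual year
    effects, observer and first-year-observer effects. Includes a
    phenology-corrected variant with decade-specific survey-date smooths linked
    by a random walk so each decade's detection peak can lead or lag the
    previous decade's, posterior summarization into area-weighted annual
    abundance indices, endpoint trends and compound percent change with
    percentile credible intervals, a synthetic survey-data generator with known
    ground truth, and a YAML-driven pipeline. MCMC sampling uses JAGS via
    rjags.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    rjags,
    coda,
    stats,
    splines,
    jsonlite,
    yaml,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
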