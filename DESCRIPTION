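Package: nutrimap
Title: Bayesian Space-Time Mapping of Child Malnutrition from Complex
    Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for district-level analysis of child (<5 years)
    malnutrition from complex panel surveys: LMS anthropometric z-scores
    and stunting/thinness-wasting/obesity classification, design-based
    (Taylor-linearized) prevalence estimation with Rao-Scott corrected
    tests of association, Moran's I spatial screening, a Bayesian
    hierarchical binomial space-time model with intrinsic CAR spatial and
    first-order random-walk temporal random effects fitted by
    Metropolis-within-Gibbs MCMC, exceedance probabilities against WHO
    2025 nutrition targets, and a synthetic-data generator emulating a
    stratified two-stage cluster panel design so the full pipeline is
    testable without restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
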