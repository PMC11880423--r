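Package: anemap
Title: Bayesian Distributional Regression Mapping of Childhood Anemia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, estimation and mapping tools for high-resolution
    childhood anemia prevalence from geo-referenced hemoglobin surveys.
    Provides a synthetic survey generator emulating cluster (PSU) sampling
    with a smooth spatial field and non-linear age effects; structured
    additive design blocks (P-splines, spatial tensor products, random
    intercepts); noncyclic gradient boosting for term selection in
    location-scale models; blockwise Metropolis-Hastings/Gibbs MCMC for
    fully Bayesian estimation of mean and scale predictors; WHO severity
    classification of anemia with altitude adjustment; pixel-level
    prevalence surfaces with credible intervals; population-weighted
    administrative aggregation, trend classification and inequality
    summaries; and predictive calibration diagnostics (PIT histograms,
    posterior prediction interval coverage, admin-level validation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
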