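# anemap

Bayesian distributional regression mapping of childhood anemia from
geo-referenced hemoglobin surveys.

## What it is for

Anemia in children aged 6–59 months is defined by hemoglobin (Hb,
altitude-adjusted) falling below WHO thresholds: any `< 110` g/L, mild
`[100, 110)`, moderate `[70, 100)`, severe `< 70` g/L. Every severity
class is an interval probability of the same continuous response, so a
model of the full conditional distribution of Hb yields all severity
prevalences coherently at any location. `anemap` is for biostatisticians
and epidemiologists who want that full pipeline on DHS-like cluster
surveys — and for method development: a synthetic-data generator with
known ground truth makes every stage testable without restricted survey
data.

The model is a structured additive location-scale (GAMLSS-type)
regression,

    y_i ~ N(mu(x_i, s_i), sigma(x_i, s_i)^2)
    mu        = sum_j f_j(x)          (identity link)
    log sigma = sum_k g_k(x)          (log link)

with linear terms, P-splines, spatial tensor-product smooths over
(lon, lat) and cluster random intercepts in either predictor. Relevant
terms are selected by noncyclic componentwise gradient boosting over both
parameters jointly (selection frequencies as importance); the selected
model is then estimated fully Bayesian by blockwise MCMC (IWLS
Gibbs/Metropolis–Hastings with inverse-gamma smoothing variances).
Severity probabilities follow from the fitted CDF, are mapped on a 20 km
pixel grid with 95% credible intervals, aggregated
population-weighted to admin-2/admin-1/country levels per posterior draw,
and validated by PIT histograms, out-of-sample 95% posterior prediction
interval (PPI) coverage and model-vs-direct admin-2 correlation.

## Worked example

```r
library(anemap)
set.seed(1)

cfg <- sim_config(n_clusters = 150, children_per_cluster = 15, seed = 11)
sim <- simulate_survey(cfg)          # survey + pixel grid + ground truth
sp  <- split_data(sim$survey, 0.8, unit = "cluster", seed = 2)

cand <- parse_terms(
  "mu ~ 1 + s(age_months) + linear(wealth_index) + te(lon, lat, k = 8)",
  "sigma ~ 1 + linear(elevation)")
sel <- select_terms(boost_select(sp$train, cand, n_iter = 200), 0.05)
sel$selected
#> [1] "mu:s(age_months)"        "mu:linear(wealth_index)"
#> [3] "mu:te(lon,lat)"

fit <- sample_posterior(sp$train, sel$terms,
                        n_iter = 3000, burnin = 500, thin = 5, seed = 3)
fit
#> anemap distributional regression fit (gaussian family)
#> 500 stored draws from 3000 iterations (burnin 500 , thin 5 )
#> terms:
#>   mu ~ 1 + s(age_months) + linear(wealth_index) + te(lon,lat)
#>   sigma ~ 1
#> acceptance rates:
#>                    mu:1        mu:s(age_months) mu:linear(wealth_index)
#>                   1.000                   1.000                   1.000
#>          mu:te(lon,lat)                 sigma:1
#>                   1.000                   0.721

pred <- predict_parameters(fit, sp$test)
ppi_coverage(sp$test$hb, pred)       # on 450 held-out children
#> [1] 0.931
```

Boosting found the three real effects (the non-linear age curve, wealth,
and residual spatial structure) and dropped the elevation scale term,
which is weak at this sample size. The acceptance rate of 1.000 on mean
blocks reflects exact Gibbs updates (conjugate under the Normal family);
the scale intercept is Metropolis–Hastings. The held-out 95% PPI coverage
of 0.931 says 93.1% of test-cluster children fell inside their 95%
posterior prediction interval — approximately calibrated.

Severity algebra and trend classification at work:

```r
severity_probabilities(mu = 100, sigma = 10)
#>       p_any    p_mild p_moderate    p_severe
#> 1 0.8413447 0.3413447  0.4986501 0.001349898

classify_trend(c(87.3, 71.9), c(77.1, 72.7))
#> [1] decrease constant
#> Levels: decrease constant increase
```

Downstream products: `predict_prevalence_surface()` (pixel maps with
credible intervals, age-stratified via `default_age_bins()`,
`mask_grid()` for exclusion rules), `marginal_curve()` (covariate effects
at a location under the 20 km buffer median/mode rule),
`aggregate_admin()` / `affected_children()` / `inequality_summary()`
(admin-level summaries per posterior draw), and `pit()` /
`admin2_validation()` (calibration).

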