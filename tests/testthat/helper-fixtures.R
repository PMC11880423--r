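# Shared fixtures.  Heavier objects are built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# A small survey with non-linear age, wealth and a spatial field: enough
# signal for qualitative recovery at low cost.
small_sim <- function(seed = 11) {
  key <- paste0("sim", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulate_survey(sim_config(
      n_clusters = 80, children_per_cluster = 15, seed = seed))
  .fixture_env[[key]]
}

# A medium fit (age spline + linear wealth on mu, intercept-only sigma)
# reused by mapping / calibration tests.
medium_fit <- function() {
  if (is.null(.fixture_env$medium)) {
    sim <- small_sim()
    terms <- parse_terms("mu ~ 1 + s(age_months) + linear(wealth_index)",
                         "sigma ~ 1")
    fit <- sample_posterior(sim$survey, terms, n_iter = 1500, burnin = 300,
                            thin = 6, seed = 42)
    .fixture_env$medium <- list(sim = sim, fit = fit)
  }
  .fixture_env$medium
}

# Flat survey: constant mu and sigma, no structure at all.
flat_config <- function(n_clusters, children_per_cluster, mu = 110,
                        sigma = 10, seed = 1) {
  sim_config(n_clusters = n_clusters,
             children_per_cluster = children_per_cluster,
             spatial_variance = 0, cluster_sd = 0,
             beta_mu = list(intercept = mu, wealth_index = 0),
             beta_sigma = list(elevation = 0),
             age_curve = function(a) rep(0, length(a)),
             sigma_baseline = sigma, seed = seed)
}
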