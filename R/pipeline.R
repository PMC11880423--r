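#' Reference calibration study: simulate, select, fit, validate, map
#'
#' Runs the full analysis pipeline once under the reference study
#' conditions and returns its validation metrics.  The stages are:
#'
#' 1. simulate a DHS-like survey ([simulate_survey()]; defaults: 250
#'    clusters of 20 children, non-linear age effect, wealth effect of
#'    3 g/L per SD and a smooth spatial field on mean hemoglobin, linear
#'    elevation effect on the log scale);
#' 2. split 80/20 by cluster ([split_data()]);
#' 3. noncyclic boosting term selection on the training part
#'    ([boost_select()], 200 iterations over age, wealth, temperature,
#'    sex and space for the mean and elevation, wealth and temperature
#'    for the scale; frequency floor 0.05);
#' 4. MCMC estimation of the selected model ([sample_posterior()];
#'    12000 iterations, 2000 burn-in, thinning 10);
#' 5. out-of-sample validation: 95% posterior-prediction-interval
#'    coverage and PIT on the held-out clusters;
#' 6. mapping and admin-2 validation: pixel prevalence surface,
#'    population-weighted aggregation to a 5 x 5 synthetic admin-2
#'    partition, and the Pearson correlation with direct survey
#'    estimates.
#'
#' @param seed Integer seed controlling every stage.
#' @param config A [sim_config()]; the default reference conditions are
#'   used when omitted.
#' @param boost_iter Boosting iterations.
#' @param frequency_floor Selection-frequency floor.
#' @param n_iter,burnin,thin MCMC settings.
#' @param quiet Suppress progress messages.
#' @return List with `coverage` (95% PPI coverage on held-out records),
#'   `rho_admin2` (model vs direct admin-2 correlation for any anemia),
#'   `pit` (calibration report), `n_test`, `fit`, `boost`, `selected`,
#'   `admin_estimates`, `direct_estimates`, and the simulated inputs.
#' @export
run_calibration_study <- function(seed = 1L, config = NULL,
                                  boost_iter = 200, frequency_floor = 0.05,
                                  n_iter = 12000, burnin = 2000, thin = 10,
                                  quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  if (is.null(config)) config <- sim_config(seed = seed)
  say("simulating survey (", config$n_clusters, " clusters x ",
      config$children_per_cluster, " children)")
  sim <- simulate_survey(config)
  sp <- split_data(sim$survey, 0.8, unit = "cluster", seed = seed + 1L)

  say("boosting term selection (", boost_iter, " iterations)")
  candidates <- parse_terms(
    paste("mu ~ 1 + s(age_months) + linear(wealth_index)",
          "+ linear(temperature) + linear(sex) + te(lon, lat)"),
    "sigma ~ 1 + linear(elevation) + linear(wealth_index) + linear(temperature)")
  br <- boost_select(sp$train, candidates, n_iter = boost_iter)
  sel <- select_terms(br, frequency_floor)
  say("selected: ", paste(sel$selected, collapse = ", "))

  say("MCMC (", n_iter, " iterations, burnin ", burnin, ", thin ", thin, ")")
  fit <- sample_posterior(sp$train, sel$terms, n_iter = n_iter,
                          burnin = burnin, thin = thin, seed = seed + 2L)

  say("out-of-sample validation on ", nrow(sp$test), " held-out records")
  pred <- predict_parameters(fit, sp$test)
  coverage <- ppi_coverage(sp$test$hb, pred, 0.95)
  pit_report <- pit(sp$test$hb, pred)

  say("mapping and admin-2 aggregation")
  grid <- mask_grid(sim$grid, config$region)
  admin <- make_admin_partition(grid, 5, 5, seed = seed + 3L)
  surf <- predict_prevalence_surface(fit, grid, severity = "any",
                                     keep_draws = TRUE)
  est <- aggregate_admin(attr(surf, "draws")$any, grid, admin, "admin2")
  model_est <- stats::setNames(est$summary$mean, est$summary$admin_id)
  direct_est <- direct_admin2_estimates(sim$survey, grid, admin, "any")
  val <- admin2_validation(model_est, direct_est)

  list(coverage = coverage, rho_admin2 = val$rho, pit = pit_report,
       n_test = nrow(sp$test), n_train = nrow(sp$train),
       fit = fit, boost = br, selected = sel$selected,
       surface = surf, admin_estimates = est,
       direct_estimates = direct_est, validation = val,
       sim = sim, split = sp, config = config)
}
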