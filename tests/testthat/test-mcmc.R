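test_that("intercept-only posterior with fixed sigma matches the conjugate closed form", {
  set.seed(14)
  n <- 200; sigma <- 8
  df <- data.frame(hb = rnorm(n, 112, sigma))
  fit <- sample_posterior(df, parse_terms("mu ~ 1"), n_iter = 2200,
                          burnin = 200, thin = 2, seed = 3,
                          fixed_sigma = sigma)
  dr <- as.numeric(fit$draws$mu[["1"]])
  # flat prior: posterior is N(ybar, sigma^2 / n); Gibbs draws are iid here
  expect_lt(abs(mean(dr) - mean(df$hb)),
            3 * sd(dr) / sqrt(length(dr)))
  ratio <- var(dr) / (sigma^2 / n)
  expect_gt(ratio, 0.9); expect_lt(ratio, 1.1)
})

test_that("the same seed reproduces the chain exactly", {
  set.seed(2)
  df <- data.frame(hb = rnorm(300, 110, 10), x = rnorm(300))
  terms <- parse_terms("mu ~ 1 + linear(x)", "sigma ~ 1")
  f1 <- sample_posterior(df, terms, n_iter = 300, burnin = 50, thin = 5,
                         seed = 77)
  f2 <- sample_posterior(df, terms, n_iter = 300, burnin = 50, thin = 5,
                         seed = 77)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$tau2, f2$tau2)
})

test_that("sampler marginals match conjugate Bayesian linear regression", {
  # no smooths, fixed sigma: the blockwise sampler must reproduce the
  # closed-form Normal posterior of a linear model with flat priors
  set.seed(6)
  n <- 300; sigma <- 5
  df <- data.frame(hb = numeric(n), x = rnorm(n))
  df$hb <- 100 + 4 * df$x + rnorm(n, 0, sigma)
  fit <- sample_posterior(df, parse_terms("mu ~ 1 + linear(x)"),
                          n_iter = 4200, burnin = 200, thin = 4, seed = 8,
                          fixed_sigma = sigma)
  # linear columns are centered at their training means, so the closed
  # form is that of the centered design
  X <- cbind(1, df$x - mean(df$x))
  V <- solve(crossprod(X)) * sigma^2
  bhat <- solve(crossprod(X), crossprod(X, df$hb))
  d_int <- as.numeric(fit$draws$mu[["1"]])
  d_slope <- as.numeric(fit$draws$mu[["linear(x)"]])
  S <- length(d_slope)
  expect_lt(abs(mean(d_int) - bhat[1]), 3 * sd(d_int) / sqrt(S / 5))
  expect_lt(abs(mean(d_slope) - bhat[2]), 3 * sd(d_slope) / sqrt(S / 5))
  for (r in c(var(d_int) / V[1, 1], var(d_slope) / V[2, 2])) {
    expect_gt(r, 0.9); expect_lt(r, 1.1)
  }
})

test_that("a linear effect on the mean is recovered with honest uncertainty", {
  cf <- flat_config(100, 10, mu = 110, sigma = 10, seed = 4)
  cf$beta_mu$wealth_index <- 3
  sim <- simulate_survey(cf)
  fit <- sample_posterior(sim$survey,
                          parse_terms("mu ~ 1 + linear(wealth_index)",
                                      "sigma ~ 1"),
                          n_iter = 1000, burnin = 200, thin = 4, seed = 5)
  dr <- as.numeric(fit$draws$mu[["linear(wealth_index)"]])
  ci <- quantile(dr, c(0.025, 0.975))
  expect_lt(abs(mean(dr) - 3), 1)
  expect_true(diff(ci) > 0)
})

test_that("acceptance bookkeeping and invariants hold", {
  mf <- medium_fit()
  fit <- mf$fit
  expect_true(all(fit$acceptance > 0 & fit$acceptance <= 1))
  # MH-updated scale intercept accepts strictly inside (0, 1)
  expect_lt(fit$acceptance[["sigma:1"]], 1)
  expect_equal(fit$meta$n_stored, (1500 - 300) %/% 6)
  expect_true(all(is.finite(unlist(fit$draws))))
  expect_true(all(fit$tau2 > 0))
  z <- geweke_diag(fit)
  expect_true(all(is.finite(z)))
})

test_that("predictions are consistent and deterministic", {
  mf <- medium_fit()
  fit <- mf$fit; sv <- mf$sim$survey
  pr_all <- predict_parameters(fit, sv[1:20, ])
  pr_one <- predict_parameters(fit, sv[c(7, 7), ])
  expect_equal(pr_one$mu[, 1], pr_one$mu[, 2])
  expect_equal(pr_one$mu[, 1], pr_all$mu[, 7])
  expect_equal(pr_one$sigma[, 1], pr_all$sigma[, 7])
})

test_that("posterior prediction intervals are nested and shrink to a point", {
  mf <- medium_fit()
  pred <- predict_parameters(mf$fit, mf$sim$survey[1:10, ])
  lv <- c(0.001, 0.2, 0.5, 0.8, 0.95)
  widths <- sapply(lv, function(l) {
    pi <- posterior_prediction_interval(pred, l)
    pi$upper - pi$lower
  })
  for (i in seq_len(10))
    expect_true(all(diff(widths[i, ]) > 0))
  expect_lt(max(widths[, 1]), 0.15)
  expect_error(posterior_prediction_interval(pred, 1.2), "level")
})

test_that("row permutation leaves posterior summaries unchanged up to MC error", {
  set.seed(10)
  df <- data.frame(hb = rnorm(400, 108, 9), x = rnorm(400))
  df$hb <- df$hb + 3 * df$x
  terms <- parse_terms("mu ~ 1 + linear(x)", "sigma ~ 1")
  f1 <- sample_posterior(df, terms, n_iter = 800, burnin = 200, thin = 3,
                         seed = 1)
  f2 <- sample_posterior(df[sample(nrow(df)), ], terms, n_iter = 800,
                         burnin = 200, thin = 3, seed = 1)
  m1 <- mean(f1$draws$mu[["linear(x)"]])
  m2 <- mean(f2$draws$mu[["linear(x)"]])
  expect_lt(abs(m1 - m2), 4 * sd(f1$draws$mu[["linear(x)"]]) / sqrt(20))
})

test_that("invalid chains and missing responses are rejected", {
  df <- data.frame(hb = rnorm(50, 110, 10))
  expect_error(sample_posterior(df, parse_terms("mu ~ 1"), n_iter = 100,
                                burnin = 100), "burnin")
  expect_error(sample_posterior(df, parse_terms("mu ~ 1"), y_col = "nope"),
               "nope")
})
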