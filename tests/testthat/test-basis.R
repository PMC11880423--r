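test_that("B-spline rows form a partition of unity and degree 0 gives indicators", {
  x <- runif(200, 3, 17)
  B <- bspline_basis(x, n_basis = 12, degree = 3)
  expect_true(all(B >= 0))
  expect_equal(rowSums(B), rep(1, 200), tolerance = 1e-10)
  B0 <- bspline_basis(x, n_basis = 8, degree = 0)
  expect_true(all(B0 %in% c(0, 1)))
  expect_equal(rowSums(B0), rep(1, 200))
  expect_error(bspline_basis(x, n_basis = 3, degree = 3), "exceed")
})

test_that("basis values match the Cox-de Boor recursion oracle", {
  x <- seq(0, 10, length.out = 101)
  B <- bspline_basis(x, n_basis = 10, degree = 3)
  knots <- attr(B, "knots")
  # oracle evaluated just inside the right boundary, as B-splines are
  # right-continuous
  xe <- pmin(x, max(x) - 1e-9)
  O <- sapply(1:10, function(j) vapply(xe, cox_de_boor, 0, j = j, ord = 4,
                                       knots = knots))
  expect_equal(unclass(B), O, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("difference penalties have the stated structure, rank and null space", {
  expect_equal(difference_penalty(2, 1), matrix(c(1, -1, -1, 1), 2))
  K <- difference_penalty(5, 2)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(ev > 1e-10), 3)       # rank n_basis - order
  expect_true(all(ev >= -1e-10))
  expect_equal(as.numeric(K %*% rep(1, 5)), rep(0, 5))   # annihilates constants
  expect_equal(as.numeric(K %*% (1:5)), rep(0, 5))       # and linear trends
  expect_error(difference_penalty(4, 4), "order")
})

test_that("tensor basis is a row-wise product with additive penalty", {
  set.seed(3)
  lon <- runif(100, 10, 20); lat <- runif(100, -5, 5)
  tb <- tensor_spatial_basis(lon, lat, n_basis = 6)
  expect_equal(ncol(tb$X), 36)
  expect_equal(rowSums(tb$X), rep(1, 100), tolerance = 1e-10)
  # constant surface in the penalty null space
  expect_equal(as.numeric(tb$K %*% rep(1, 36)), rep(0, 36), tolerance = 1e-10)
  ev <- eigen(tb$K, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-10))
  expect_error(tensor_spatial_basis(lon, lat[-1]), "length")
})

test_that("build_design bookkeeping: dimensions, ordering, unknown covariates", {
  set.seed(8)
  df <- data.frame(hb = rnorm(50, 110, 10), age = runif(50, 6, 59),
                   wealth = rnorm(50))
  d0 <- build_design(df, parse_terms("mu ~ 1"))
  expect_named(d0, "mu")
  expect_length(d0$mu, 1L)
  expect_equal(ncol(d0$mu[[1]]$X), 1L)
  terms <- parse_terms("mu ~ 1 + s(age, k = 20) + linear(wealth)")
  d <- build_design(df, terms)
  expect_equal(vapply(d$mu, function(b) ncol(b$X), 0L), c(1L, 20L, 1L))
  # linear term column is the covariate itself
  expect_equal(as.numeric(d$mu[[3]]$X), df$wealth)
  expect_error(build_design(df, parse_terms("mu ~ linear(nope)")), "nope")
})

test_that("all constrained penalties are PSD and constraints center the smooth", {
  sim <- small_sim()
  terms <- parse_terms(
    "mu ~ 1 + s(age_months) + te(lon, lat, k = 6) + ri(cluster_id)",
    "sigma ~ 1 + linear(elevation)")
  d <- build_design(sim$survey, terms)
  for (p in names(d)) for (b in d[[p]]) {
    if (is.null(b$K)) next
    ev <- eigen(b$KZ, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1e-10))
    # constrained smooths have zero training-sample sum for any coefficient
    if (b$term$kind %in% c("pspline", "spatial_tensor")) {
      bvec <- rnorm(ncol(b$XZ))
      expect_lt(abs(sum(b$XZ %*% bvec)), 1e-6)
    }
  }
})

test_that("stored knots reproduce the training design exactly", {
  sim <- small_sim()
  terms <- parse_terms("mu ~ 1 + s(age_months) + te(lon, lat, k = 6)")
  d <- build_design(sim$survey, terms)
  for (b in d$mu)
    expect_equal(eval_block(b, sim$survey), unname(b$XZ), tolerance = 1e-12)
})

test_that("out-of-range prediction clamps to the boundary with a warning", {
  x <- runif(100, 0, 10)
  B <- bspline_basis(x, 10, 3)
  expect_warning(B2 <- bspline_basis(c(-5, 5, 15), 10, 3,
                                     knots = attr(B, "knots")),
                 "clamped")
  B_edge <- bspline_basis(c(min(x), 5, max(x)), 10, 3,
                          knots = attr(B, "knots"))
  expect_equal(unclass(B2), unclass(B_edge), tolerance = 1e-9)
})

test_that("formula strings round-trip through parse and format", {
  terms <- parse_terms("mu ~ 1 + linear(wealth) + s(age, k = 15) + te(lon, lat)",
                       "sigma ~ 1 + linear(elev)")
  expect_length(terms, 6L)
  expect_equal(terms[[3]]$n_basis, 15L)
  fml <- format_terms(terms)
  expect_match(fml[["mu"]], "s\\(age\\)")
  expect_match(fml[["sigma"]], "linear\\(elev\\)")
  expect_error(parse_terms("mu ~ wiggle(x)"), "unknown term")
})
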