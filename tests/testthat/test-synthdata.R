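test_that("pixel grids cover the box at the requested resolution", {
  # bbox chosen to span exactly 100 km x 100 km at the equator
  bbox <- c(0, 100 / 111.320, -50 / 110.574, 50 / 110.574)
  g <- make_pixel_grid(bbox, 20)
  expect_equal(nrow(g), 25L)
  expect_equal(attr(g, "n_lon"), 5L)
  # default resolution is 20 km
  expect_equal(attr(make_pixel_grid(bbox), "resolution_km"), 20)
  # one-pixel box
  g1 <- make_pixel_grid(c(0, 0.1, 0, 0.1), 20)
  expect_equal(nrow(g1), 1L)
  expect_error(make_pixel_grid(c(0, 0, 0, 1), 20), "bbox")
  expect_error(make_pixel_grid(bbox, -5), "positive")
  expect_true(all(c("elevation", "temperature", "landcover", "population",
                    "mask_flag") %in% names(g)))
})

test_that("spatial fields are deterministic, zero at zero variance, and hit the target variance", {
  # 50 x 50 pixels: 1000 km x 1000 km centered on the equator at 20 km
  g <- make_pixel_grid(c(10, 10 + 1000 / 111.320,
                         -500 / 110.574, 500 / 110.574), 20)
  expect_equal(nrow(g), 2500L)
  expect_equal(simulate_spatial_field(g, 0, 200, seed = 3),
               rep(0, nrow(g)))
  f1 <- simulate_spatial_field(g, 25, 200, seed = 3)
  f2 <- simulate_spatial_field(g, 25, 200, seed = 3)
  expect_identical(f1, f2)
  expect_false(identical(f1, simulate_spatial_field(g, 25, 200, seed = 4)))
  expect_error(simulate_spatial_field(g, -1, 200), "variance")

  # replicate-simulation oracle: average pixel variance ~ 25
  reps <- vapply(1:200, function(s)
    mean(simulate_spatial_field(g, 25, 200, seed = 100 + s)^2), 0)
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 25), 3 * se)
  # fields average out near zero
  m <- vapply(1:200, function(s)
    mean(simulate_spatial_field(g, 25, 200, seed = 100 + s)), 0)
  expect_lt(abs(mean(m)), 3 * sd(m) / sqrt(length(m)))
})

test_that("survey generation is reproducible and respects record invariants", {
  cf <- sim_config(n_clusters = 30, children_per_cluster = 8, seed = 5)
  s1 <- simulate_survey(cf)
  s2 <- simulate_survey(cf)
  expect_identical(s1$survey, s2$survey)
  sv <- s1$survey
  expect_true(all(sv$hb > 0))
  expect_true(all(sv$age_months >= 6 & sv$age_months <= 59))
  expect_true(all(sv$lon >= cf$bbox[1] & sv$lon <= cf$bbox[2]))
  expect_true(all(sv$lat >= cf$bbox[3] & sv$lat <= cf$bbox[4]))
  # PSU members share one geo-coordinate
  expect_true(all(tapply(sv$lon, sv$cluster_id, function(x)
    length(unique(x))) == 1))
  expect_error(sim_config(n_clusters = 1), "n_clusters")
  expect_error(sim_config(spatial_variance = -2), "spatial_variance")
})

test_that("the noise-free limit returns the mean surface", {
  cf <- sim_config(n_clusters = 20, children_per_cluster = 5,
                   sigma_baseline = exp(-10),
                   beta_sigma = list(elevation = 0), seed = 2)
  sim <- simulate_survey(cf)
  expect_lt(max(abs(sim$survey$hb - sim$survey$true_mu)), 1e-3)
})

test_that("flat configurations reproduce the configured Normal (CLT and KS)", {
  sim <- simulate_survey(flat_config(2500, 20, mu = 110, sigma = 10, seed = 6))
  expect_equal(nrow(sim$survey), 50000L)
  expect_lt(abs(mean(sim$survey$hb) - 110), 3 * 10 / sqrt(50000))
  sim2 <- simulate_survey(flat_config(500, 20, mu = 105, sigma = 12, seed = 9))
  ks <- ks.test(sim2$survey$hb, "pnorm", 105, 12)
  expect_gt(ks$p.value, 0.01)
})

test_that("ground-truth prevalence matches a Monte-Carlo estimate", {
  cf <- sim_config(n_clusters = 10, children_per_cluster = 5, seed = 3)
  sim <- simulate_survey(cf)
  px <- 137
  mu_base <- sim$truth$true_mu_surface[px] -
    mean(as.numeric(cf$age_curve(6:59)))
  sigma <- sim$truth$true_sigma_surface[px]
  n <- 1e5
  set.seed(21)
  ages <- sample(6:59, n, replace = TRUE)
  hb <- rnorm(n, mu_base + as.numeric(cf$age_curve(ages)), sigma)
  p_emp <- mean(hb < 110)
  p_true <- sim$truth$true_prevalence$p_any[px]
  expect_lt(abs(p_emp - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
  # severity classes sum to the any-anemia probability per pixel
  tp <- sim$truth$true_prevalence
  expect_equal(tp$p_mild + tp$p_moderate + tp$p_severe, tp$p_any,
               tolerance = 1e-12)
  expect_true(all(as.matrix(tp) >= 0 & as.matrix(tp) <= 1))
})

test_that("admin partitions are exhaustive, disjoint and nested", {
  g <- make_pixel_grid(c(10, 15, -2, 2), 25)
  adm <- make_admin_partition(g, n_level1 = 3, n_level2_per_level1 = 4,
                              seed = 8)
  expect_setequal(adm$pixel_id, g$pixel_id)
  expect_equal(anyDuplicated(adm$pixel_id), 0L)
  # every admin-2 belongs to exactly one admin-1
  expect_true(all(tapply(adm$admin1_id, adm$admin2_id, function(x)
    length(unique(x))) == 1))
  expect_equal(length(unique(adm$admin1_id)), 3L)
  # trivial single-region partition
  adm1 <- make_admin_partition(g, 1, 1, seed = 1)
  expect_equal(length(unique(adm1$admin2_id)), 1L)
  expect_error(make_admin_partition(g[1:3, ], 2, 2), "more admin regions")
})

test_that("CSV writers round-trip the simulated objects", {
  sim <- simulate_survey(sim_config(n_clusters = 5, children_per_cluster = 3,
                                    seed = 1))
  tmp <- withr::local_tempdir()
  p1 <- write_survey_csv(sim, file.path(tmp, "survey.csv"))
  sv <- read.csv(p1)
  expect_equal(nrow(sv), nrow(sim$survey))
  expect_false(any(c("true_mu", "true_sigma") %in% names(sv)))
  p2 <- write_grid_csv(sim$grid, file.path(tmp, "grid.csv"))
  expect_equal(nrow(read.csv(p2)), nrow(sim$grid))
  adm <- make_admin_partition(sim$grid, 2, 2, seed = 2)
  p3 <- write_admin_csv(adm, file.path(tmp, "admin.csv"))
  expect_equal(read.csv(p3)$admin2_id, adm$admin2_id)
})
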