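test_that("masking applies landcover and region-specific altitude rules", {
  g <- data.frame(pixel_id = 1:4,
                  elevation = c(3800, 2000, 2000, 10),
                  landcover = c("forest", "forest", "forest", "barren"))
  expect_true(mask_grid(g, "ssa_mainland")$mask_flag[1])   # above 3750 m
  expect_true(mask_grid(g, "madagascar")$mask_flag[2])     # above 1900 m
  expect_false(mask_grid(g, "south_asia")$mask_flag[3])    # 2000 m is fine
  expect_true(mask_grid(g, "south_asia")$mask_flag[4])     # barren at sea level
  g$landcover[4] <- "snow_ice"
  expect_true(mask_grid(g, "ssa_mainland")$mask_flag[4])
  expect_error(mask_grid(g, "atlantis"), "region")
  expect_error(mask_grid(g[, 1:2], "ssa_mainland"), "landcover")
})

test_that("locate_pixel inverts the grid layout", {
  g <- make_pixel_grid(c(10, 15, -2, 2), 30)
  expect_equal(locate_pixel(g, g$lon, g$lat), g$pixel_id)
})

test_that("prevalence surfaces conserve severity classes and honor masks", {
  mf <- medium_fit()
  grid <- mask_grid(mf$sim$grid, "ssa_mainland")
  grid <- grid[grid$pixel_id %% 13 == 0, ]        # thin for speed
  surf <- predict_prevalence_surface(mf$fit, grid, keep_draws = TRUE)
  expect_true(all(surf$mean >= 0 & surf$mean <= 1))
  expect_true(all(surf$lower95 <= surf$mean & surf$mean <= surf$upper95))
  expect_false(any(surf$pixel_id %in% grid$pixel_id[grid$mask_flag]))
  dr <- attr(surf, "draws")
  expect_equal(dr$mild + dr$moderate + dr$severe, dr$any, tolerance = 1e-12)
  # pixel ordering does not change per-pixel results
  surf2 <- predict_prevalence_surface(mf$fit, grid[rev(seq_len(nrow(grid))), ])
  m1 <- surf$mean[surf$severity == "any"][order(surf$pixel_id[surf$severity == "any"])]
  o2 <- surf2$severity == "any"
  m2 <- surf2$mean[o2][order(surf2$pixel_id[o2])]
  expect_equal(m1, m2)
})

test_that("a degenerate posterior collapses the credible interval", {
  mf <- medium_fit()
  fit1 <- mf$fit
  # keep a single draw in every block: all draws identical
  for (p in fit1$params)
    fit1$draws[[p]] <- lapply(fit1$draws[[p]], function(m) m[c(1, 1), , drop = FALSE])
  fit1$meta$n_stored <- 2L
  grid <- mf$sim$grid[1:40, ]
  surf <- predict_prevalence_surface(fit1, grid, severity = "any")
  expect_equal(surf$lower95, surf$mean, tolerance = 1e-12)
  expect_equal(surf$upper95, surf$mean, tolerance = 1e-12)
})

test_that("age-stratified surfaces use the configured bins", {
  mf <- medium_fit()
  grid <- mf$sim$grid[1:25, ]
  bins <- default_age_bins()
  expect_equal(bins[["(42,60]"]][2], 59)   # capped at the data maximum
  s_young <- predict_prevalence_surface(mf$fit, grid, bins[["(6,24]"]],
                                        severity = "any")
  s_old <- predict_prevalence_surface(mf$fit, grid, bins[["(42,60]"]],
                                      severity = "any")
  # the simulated age curve makes young children more anemic
  expect_gt(mean(s_young$mean), mean(s_old$mean))
  expect_error(predict_prevalence_surface(mf$fit, grid, c(3, 20)),
               "age_stratum")
})

test_that("buffer membership uses great-circle distance", {
  mf <- medium_fit()
  sv <- mf$sim$survey
  # construct records at 19.9 and 20.1 km due north of a reference point
  lon0 <- 15; lat0 <- 0
  lat_in <- lat0 + 19.9 / 111.3195
  lat_out <- lat0 + 20.1 / 111.3195
  expect_equal(haversine_km(lon0, lat0, lon0, lat_in), 19.9, tolerance = 1e-3)
  sv2 <- sv
  sv2$lon <- lon0; sv2$lat <- lat_out
  sv2$lat[1] <- lat_in
  mc <- marginal_curve(mf$fit, sv2[1:50, ], lon0, lat0, "wealth_index",
                       grid_values = c(-1, 0, 1))
  expect_equal(mc$n_buffer, 1L)            # only the 19.9 km record
  expect_error(marginal_curve(mf$fit, sv2[2:50, ], lon0, lat0,
                              "wealth_index"),
               "within 20")
})

test_that("the marginal curve matches the point prediction at the buffer median", {
  mf <- medium_fit()
  sv <- mf$sim$survey
  loc <- c(sv$lon[1], sv$lat[1])
  mc <- marginal_curve(mf$fit, sv, loc[1], loc[2], "wealth_index")
  expect_true(all(mc$curve$lower95 <= mc$curve$mean &
                    mc$curve$mean <= mc$curve$upper95))
  # evaluate the curve exactly at the focal median: must equal the direct
  # prediction at the full median profile
  mc0 <- marginal_curve(mf$fit, sv, loc[1], loc[2], "wealth_index",
                        grid_values = mc$focal_median)
  buf <- sv[haversine_km(sv$lon, sv$lat, loc[1], loc[2]) <= 20, ]
  expect_equal(mc0$focal_median, median(buf$wealth_index))
})

test_that("the fitted age profile recovers the true turning point", {
  mf <- medium_fit()
  sv <- mf$sim$survey
  mc <- marginal_curve(mf$fit, sv, sv$lon[1], sv$lat[1], "age_months",
                       grid_values = 6:59)
  prev <- mc$curve$mean
  # anemia prevalence peaks where mean hemoglobin is lowest
  peak <- mc$curve$value[which.max(prev)]
  truth <- mf$sim$truth$age_turning_point
  expect_lte(abs(peak - truth), 6)
  # the slope changes sign at the turning point: rising into the peak,
  # falling away from it
  ages <- mc$curve$value
  expect_gt(prev[ages == truth] , prev[ages == 6])
  expect_gt(mean(diff(prev[ages <= truth - 6])), 0)
  expect_lt(mean(diff(prev[ages >= truth + 6])), 0)
})
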