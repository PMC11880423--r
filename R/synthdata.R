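#' Default non-linear age effect on mean hemoglobin
#'
#' Piecewise-smooth curve (g/L, centered effect) with its minimum at 18
#' months and a rise thereafter, mirroring the qualitative age profile of
#' childhood anemia: hemoglobin is lowest in the second year of life and
#' recovers with age.  The two parabolic arms share a zero derivative at
#' the minimum; the left arm is steeper so the dip is pronounced (about
#' 8 g/L between 6 and 18 months, 15 g/L between 18 and 59 months).  The
#' turning point is exposed as attribute `"turning_point"` so recovery
#' tests can check against the truth.
#'
#' @param age_months Age in months.
#' @return Effect on mean hemoglobin, g/L.
#' @export
default_age_curve <- function(age_months) {
  a <- age_months
  structure(ifelse(a < 18, 8 * ((18 - a) / 12)^2, 15 * ((a - 18) / 41)^2) - 5,
            turning_point = 18)
}
attr(default_age_curve, "turning_point") <- 18

#' Simulation configuration for DHS-like hemoglobin surveys
#'
#' Bundles every knob of the synthetic survey generator.  The defaults are
#' the reference study conditions used throughout the package's recovery
#' experiments: 250 clusters (primary sampling units) of 20 children each
#' over a roughly 1100 x 1100 km region, a smooth spatial field on mean
#' hemoglobin with variance 25 (g/L)^2 and 200 km range, a strongly
#' non-linear age effect, a wealth effect of 3 g/L per SD on the mean, an
#' elevation effect on the log scale, baseline scale 10 g/L, and an i.i.d.
#' cluster random intercept (SD 2 g/L) emulating multistage-sampling
#' dependence.
#'
#' @param n_clusters Number of survey clusters (>= 2).
#' @param children_per_cluster Children measured per cluster (>= 1).
#' @param bbox Numeric `c(lon_min, lon_max, lat_min, lat_max)`, degrees.
#' @param spatial_variance Marginal variance of the spatial field, (g/L)^2.
#' @param spatial_range_km Correlation range of the spatial field, km.
#' @param beta_mu Named list of linear effects on mean hemoglobin (g/L per
#'   covariate unit): `intercept`, `wealth_index` (per SD), `temperature`
#'   (per degree C, centered), `sex_male` (contrast), `survey_year` (per
#'   year, centered).
#' @param beta_sigma Named list of linear effects on log scale:
#'   `elevation` (per meter, centered at the regional mean elevation).
#' @param age_curve Function months -> g/L (non-linear age effect on the
#'   mean); default [default_age_curve()].
#' @param sigma_baseline Baseline scale, g/L (log-link intercept is
#'   `log(sigma_baseline)`).
#' @param cluster_sd SD of the cluster random intercept, g/L (0 switches
#'   the cluster effect off).  The within-PSU dependence structure of real
#'   surveys is unknown; an i.i.d. Normal intercept is an explicit
#'   stand-in.
#' @param resolution_km Pixel size of the companion prediction grid.
#' @param survey_year Calendar year(s); clusters are assigned years
#'   uniformly when more than one is given.
#' @param region Region label (`ssa_mainland`, `south_asia`,
#'   `madagascar`).
#' @param seed Integer seed; the same config and seed reproduce the survey
#'   exactly.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_clusters = 250,
                       children_per_cluster = 20,
                       bbox = c(10, 20, -5, 5),
                       spatial_variance = 25,
                       spatial_range_km = 200,
                       beta_mu = list(),
                       beta_sigma = list(),
                       age_curve = default_age_curve,
                       sigma_baseline = 10,
                       cluster_sd = 2,
                       resolution_km = 20,
                       survey_year = 2015,
                       region = "ssa_mainland",
                       seed = 1L) {
  if (n_clusters < 2) stop("n_clusters must be >= 2")
  if (children_per_cluster < 1) stop("children_per_cluster must be >= 1")
  if (spatial_variance < 0) stop("spatial_variance must be >= 0")
  if (length(bbox) != 4 || bbox[2] <= bbox[1] || bbox[4] <= bbox[3])
    stop("bbox must be a non-degenerate c(lon_min, lon_max, lat_min, lat_max)")
  if (sigma_baseline <= 0) stop("sigma_baseline must be positive")
  region <- match.arg(region, c("ssa_mainland", "south_asia", "madagascar"))
  bm <- list(intercept = 108, wealth_index = 3, temperature = 0,
             sex_male = 0, survey_year = 0)
  bm[names(beta_mu)] <- beta_mu
  bs <- list(elevation = 1.5e-4)
  bs[names(beta_sigma)] <- beta_sigma
  structure(list(n_clusters = as.integer(n_clusters),
                 children_per_cluster = as.integer(children_per_cluster),
                 bbox = as.numeric(bbox),
                 spatial_variance = spatial_variance,
                 spatial_range_km = spatial_range_km,
                 beta_mu = bm, beta_sigma = bs,
                 age_curve = age_curve,
                 sigma_baseline = sigma_baseline,
                 cluster_sd = cluster_sd,
                 resolution_km = resolution_km,
                 survey_year = as.integer(survey_year),
                 region = region,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# --- deterministic environmental surfaces -------------------------------
# Smooth functions of normalized position shared by the pixel grid and the
# survey clusters, so interpolation between the two is never needed.

norm_uv <- function(lon, lat, bbox) {
  list(u = (lon - bbox[1]) / (bbox[2] - bbox[1]),
       v = (lat - bbox[3]) / (bbox[4] - bbox[3]))
}

elevation_surface <- function(lon, lat, bbox) {
  p <- norm_uv(lon, lat, bbox)
  600 + 500 * sin(pi * p$u) * cos(pi * p$v) + 300 * p$v
}

temperature_surface <- function(lon, lat, bbox) {
  elev <- elevation_surface(lon, lat, bbox)
  32 - 6.5 * elev / 1000 + 2 * sin(2 * pi * norm_uv(lon, lat, bbox)$u)
}

landcover_surface <- function(lon, lat, bbox) {
  p <- norm_uv(lon, lat, bbox)
  elev <- elevation_surface(lon, lat, bbox)
  ifelse(elev > 1350, "barren",
         ifelse(sin(3 * pi * p$u + 2 * p$v) > 0.3, "cropland", "forest"))
}

population_surface <- function(lon, lat, bbox) {
  p <- norm_uv(lon, lat, bbox)
  500 + 4000 * exp(-((p$u - 0.45)^2 + (p$v - 0.55)^2) / 0.08)
}

#' Regular pixel grid over a bounding box
#'
#' Lays a regular grid of square-ish pixels (default 20 km) over the
#' bounding box and fills in the deterministic synthetic covariate
#' surfaces: elevation, 2 m air temperature, land-cover class and
#' population of children aged 6-59 months.  Pixel counts per axis are the
#' smallest integers whose pixels cover the box at the requested
#' resolution (degrees are converted to km at the box mid-latitude).
#'
#' @param bbox `c(lon_min, lon_max, lat_min, lat_max)`, degrees WGS84.
#' @param resolution_km Target pixel edge length in km (> 0).
#' @return A data.frame of class `pixel_grid` with one row per pixel:
#'   `pixel_id`, centroid `lon`/`lat`, `area_km2`, `elevation`,
#'   `temperature`, `landcover`, `population`, `mask_flag`.
#' @export
make_pixel_grid <- function(bbox, resolution_km = 20) {
  if (resolution_km <= 0) stop("resolution_km must be positive")
  if (length(bbox) != 4 || bbox[2] <= bbox[1] || bbox[4] <= bbox[3])
    stop("bbox must be non-degenerate")
  mid_lat <- (bbox[3] + bbox[4]) / 2
  km_lon <- 111.320 * cos(mid_lat * pi / 180)
  km_lat <- 110.574
  width_km <- (bbox[2] - bbox[1]) * km_lon
  height_km <- (bbox[4] - bbox[3]) * km_lat
  n_lon <- max(1L, as.integer(ceiling(width_km / resolution_km - 1e-9)))
  n_lat <- max(1L, as.integer(ceiling(height_km / resolution_km - 1e-9)))
  d_lon <- (bbox[2] - bbox[1]) / n_lon
  d_lat <- (bbox[4] - bbox[3]) / n_lat
  cent_lon <- bbox[1] + (seq_len(n_lon) - 0.5) * d_lon
  cent_lat <- bbox[3] + (seq_len(n_lat) - 0.5) * d_lat
  g <- expand.grid(lon = cent_lon, lat = cent_lat,
                   KEEP.OUT.ATTRS = FALSE)
  grid <- data.frame(pixel_id = seq_len(nrow(g)), lon = g$lon, lat = g$lat,
                     area_km2 = d_lon * km_lon * d_lat * km_lat)
  grid$elevation <- elevation_surface(grid$lon, grid$lat, bbox)
  grid$temperature <- temperature_surface(grid$lon, grid$lat, bbox)
  grid$landcover <- landcover_surface(grid$lon, grid$lat, bbox)
  grid$population <- population_surface(grid$lon, grid$lat, bbox)
  grid$mask_flag <- FALSE
  structure(grid, bbox = bbox, resolution_km = resolution_km,
            n_lon = n_lon, n_lat = n_lat, d_lon = d_lon, d_lat = d_lat,
            class = c("pixel_grid", "data.frame"))
}

# Low-rank smooth Gaussian random field as a closure over (lon, lat).
# Gaussian bump basis on a coarse knot lattice with i.i.d. N(0, 1)
# coefficients; rows are rescaled so the pointwise marginal variance is
# exactly `variance` everywhere.  Smoothness, not covariance exactness, is
# what downstream stages need.
spatial_field_fun <- function(bbox, variance, range_km, seed) {
  if (variance < 0) stop("spatial field variance must be >= 0")
  mid_lat <- (bbox[3] + bbox[4]) / 2
  km_lon <- 111.320 * cos(mid_lat * pi / 180)
  km_lat <- 110.574
  spacing <- range_km / 1.5
  kx <- seq(bbox[1] - range_km / km_lon, bbox[2] + range_km / km_lon,
            by = spacing / km_lon)
  ky <- seq(bbox[3] - range_km / km_lat, bbox[4] + range_km / km_lat,
            by = spacing / km_lat)
  knots <- expand.grid(lon = kx, lat = ky, KEEP.OUT.ATTRS = FALSE)
  gamma <- with_seed(seed, stats::rnorm(nrow(knots)))
  function(lon, lat) {
    if (variance == 0) return(rep(0, length(lon)))
    dx <- outer(lon * km_lon, knots$lon * km_lon, "-")
    dy <- outer(lat * km_lat, knots$lat * km_lat, "-")
    B <- exp(-(dx^2 + dy^2) / (2 * (range_km / 2)^2))
    v <- rowSums(B^2)
    as.numeric(B %*% gamma) * sqrt(variance / v)
  }
}

#' Simulate a smooth spatial field on a pixel grid
#'
#' Draws one realization of the low-rank Gaussian field used for residual
#' spatial heterogeneity in mean hemoglobin.  The field has mean zero and
#' pointwise variance exactly `variance`; `variance = 0` returns exact
#' zeros, and the same seed reproduces the same field.
#'
#' @param grid A [make_pixel_grid()] grid (non-empty).
#' @param variance Marginal variance, (g/L)^2; must be >= 0.
#' @param range_km Correlation range in km.
#' @param seed Integer seed.
#' @return Numeric vector, one value per pixel.
#' @export
simulate_spatial_field <- function(grid, variance, range_km, seed = 1L) {
  stopifnot(nrow(grid) > 0)
  if (variance < 0) stop("spatial field variance must be >= 0")
  spatial_field_fun(attr(grid, "bbox") %||%
                      c(min(grid$lon), max(grid$lon),
                        min(grid$lat), max(grid$lat)),
                    variance, range_km, seed)(grid$lon, grid$lat)
}

#' Simulate a DHS-like geo-referenced hemoglobin survey
#'
#' Generates child-level records under the location-scale model the
#' package estimates: mean hemoglobin is the sum of an intercept, the
#' non-linear age curve, linear covariate effects, a smooth spatial field
#' and a cluster random intercept; log scale is linear in (centered)
#' elevation; hemoglobin is then drawn from the Normal family.  Cluster
#' members share one geo-coordinate (PSU sampling).  The companion pixel
#' grid and full ground truth (true surfaces, coefficients and closed-form
#' severity prevalence per pixel) are returned alongside.
#'
#' The ground-truth surfaces and prevalences use the map-product covariate
#' profile: prevalence averaged over integer ages 6-59 months with
#' non-geo-referenced covariates fixed at their population medians.
#'
#' @param config A [sim_config()].
#' @return A list of class `anemap_sim` with elements `survey`
#'   (data.frame of `SurveyRecord`s), `grid` (pixel grid) and `truth`
#'   (list: `true_mu_surface`, `true_sigma_surface`, `true_field`,
#'   `true_coefficients`, `true_prevalence`, `age_turning_point`).
#' @export
simulate_survey <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  bbox <- cf$bbox
  grid <- make_pixel_grid(bbox, cf$resolution_km)
  field <- spatial_field_fun(bbox, cf$spatial_variance, cf$spatial_range_km,
                             seed = cf$seed + 1000L)
  elev_ref <- mean(grid$elevation)
  temp_ref <- mean(grid$temperature)
  year_ref <- mean(cf$survey_year)

  survey <- with_seed(cf$seed, {
    nc <- cf$n_clusters
    m <- cf$children_per_cluster
    cl_lon <- stats::runif(nc, bbox[1], bbox[2])
    cl_lat <- stats::runif(nc, bbox[3], bbox[4])
    cl_re <- stats::rnorm(nc, 0, cf$cluster_sd)
    cl_wealth <- stats::rnorm(nc, 0, 0.7)
    cl_year <- if (length(cf$survey_year) == 1L) rep(cf$survey_year, nc)
               else sample(cf$survey_year, nc, replace = TRUE)
    idx <- rep(seq_len(nc), each = m)
    n <- nc * m
    age <- sample(6:59, n, replace = TRUE)
    sex <- factor(sample(c("female", "male"), n, replace = TRUE),
                  levels = c("female", "male"))
    wealth <- cl_wealth[idx] + stats::rnorm(n, 0, sqrt(1 - 0.49))
    lon <- cl_lon[idx]; lat <- cl_lat[idx]
    elev <- elevation_surface(lon, lat, bbox)
    temp <- temperature_surface(lon, lat, bbox)
    year <- cl_year[idx]
    mu <- cf$beta_mu$intercept +
      as.numeric(cf$age_curve(age)) +
      cf$beta_mu$wealth_index * wealth +
      cf$beta_mu$temperature * (temp - temp_ref) +
      cf$beta_mu$sex_male * (sex == "male") +
      cf$beta_mu$survey_year * (year - year_ref) +
      field(lon, lat) + cl_re[idx]
    log_sigma <- log(cf$sigma_baseline) +
      cf$beta_sigma$elevation * (elev - elev_ref)
    data.frame(hb = stats::rnorm(n, mu, exp(log_sigma)),
               age_months = age, sex = sex, wealth_index = wealth,
               elevation = elev, temperature = temp,
               cluster_id = sprintf("PSU%03d", idx),
               lon = lon, lat = lat, survey_year = year,
               region = cf$region,
               true_mu = mu, true_sigma = exp(log_sigma))
  })

  truth <- ground_truth(cf, grid, field, elev_ref, temp_ref)
  structure(list(survey = survey, grid = grid, truth = truth,
                 config = cf), class = "anemap_sim")
}

# Closed-form ground truth on the pixel grid at the map-product profile.
ground_truth <- function(cf, grid, field, elev_ref, temp_ref) {
  ages <- 6:59
  age_eff <- mean(as.numeric(cf$age_curve(ages)))
  f <- field(grid$lon, grid$lat)
  mu <- cf$beta_mu$intercept + age_eff + f +
    cf$beta_mu$temperature * (grid$temperature - temp_ref)
  sigma <- exp(log(cf$sigma_baseline) +
                 cf$beta_sigma$elevation * (grid$elevation - elev_ref))
  # per-pixel prevalence averaged over integer ages (wealth/sex at median)
  prev <- matrix(0, nrow(grid), 4L,
                 dimnames = list(NULL, c("p_any", "p_mild", "p_moderate",
                                         "p_severe")))
  base_mu <- mu - age_eff
  for (a in ages) {
    sp <- severity_probabilities(base_mu + as.numeric(cf$age_curve(a)), sigma)
    prev <- prev + as.matrix(sp) / length(ages)
  }
  list(true_mu_surface = mu, true_sigma_surface = sigma, true_field = f,
       true_coefficients = c(cf$beta_mu[-1], list(sigma = cf$beta_sigma)),
       true_prevalence = as.data.frame(prev),
       age_turning_point = attr(cf$age_curve, "turning_point") %||% NA_real_)
}

#' Partition a pixel grid into nested administrative units
#'
#' Builds a synthetic admin hierarchy by k-means clustering of pixel
#' centroids: `n_level1` admin-1 regions, each split into
#' `n_level2_per_level1` admin-2 regions, all nested in one country.  The
#' partition is exhaustive and disjoint, and deterministic under the seed.
#'
#' @param grid A pixel grid.
#' @param n_level1 Number of admin-1 units (>= 1).
#' @param n_level2_per_level1 Admin-2 units per admin-1 (>= 1).
#' @param seed Integer seed.
#' @return A data.frame `pixel_id`, `country`, `admin1_id`, `admin2_id`.
#' @export
make_admin_partition <- function(grid, n_level1, n_level2_per_level1,
                                 seed = 1L) {
  if (n_level1 < 1 || n_level2_per_level1 < 1)
    stop("admin unit counts must be >= 1")
  if (n_level1 * n_level2_per_level1 > nrow(grid))
    stop("more admin regions requested than pixels available")
  xy <- cbind(grid$lon, grid$lat)
  a1 <- with_seed(seed, {
    if (n_level1 == 1L) rep(1L, nrow(grid))
    else stats::kmeans(xy, centers = n_level1, nstart = 5,
                       iter.max = 50)$cluster
  })
  a2 <- integer(nrow(grid))
  for (j in seq_len(n_level1)) {
    sel <- which(a1 == j)
    if (length(sel) < n_level2_per_level1)
      stop("admin-1 unit ", j, " has fewer pixels than requested admin-2 units")
    a2[sel] <- with_seed(seed + j, {
      if (n_level2_per_level1 == 1L) rep(1L, length(sel))
      else stats::kmeans(xy[sel, , drop = FALSE],
                         centers = n_level2_per_level1, nstart = 5,
                         iter.max = 50)$cluster
    })
  }
  data.frame(pixel_id = grid$pixel_id,
             country = "SYN",
             admin1_id = sprintf("A1_%02d", a1),
             admin2_id = sprintf("A2_%02d_%02d", a1, a2))
}

#' Write simulation outputs as plain-text files
#'
#' `write_survey_csv()` writes the child-level records, `write_grid_csv()`
#' one row per pixel (centroid, covariates, population, mask), and
#' `write_admin_csv()` the pixel-to-admin lookup table.
#'
#' @param sim An `anemap_sim` (or a survey data.frame).
#' @param grid A pixel grid.
#' @param admin An admin partition data.frame.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_survey_csv <- function(sim, path) {
  df <- if (inherits(sim, "anemap_sim")) sim$survey else sim
  utils::write.csv(df[setdiff(names(df), c("true_mu", "true_sigma"))],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
write_grid_csv <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
write_admin_csv <- function(admin, path) {
  utils::write.csv(admin, path, row.names = FALSE)
  invisible(path)
}
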