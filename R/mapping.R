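#' Flag pixels excluded from map products
#'
#' Masks pixels that are barren or permanent snow/ice, and pixels above
#' the region-specific altitude limit: 3750 m for mainland sub-Saharan
#' Africa and South Asia, 1900 m for Madagascar.
#'
#' @param grid A pixel grid with `elevation` and `landcover` columns.
#' @param region One of `"ssa_mainland"`, `"south_asia"`, `"madagascar"`.
#' @return The grid with `mask_flag` set.
#' @export
mask_grid <- function(grid, region) {
  if (is.null(grid$elevation) || is.null(grid$landcover))
    stop("grid must carry elevation and landcover")
  if (!region %in% c("ssa_mainland", "south_asia", "madagascar"))
    stop("unknown region label: ", region)
  limit <- if (region == "madagascar") 1900 else 3750
  grid$mask_flag <- grid$landcover %in% c("barren", "snow_ice") |
    grid$elevation > limit
  grid
}

#' Locate survey coordinates on a regular pixel grid
#'
#' Maps (lon, lat) points to the pixel id of the regular grid cell that
#' contains them (points outside the bounding box are clamped to the edge
#' pixel).
#'
#' @param grid A [make_pixel_grid()] grid.
#' @param lon,lat Coordinate vectors, degrees.
#' @return Integer vector of pixel ids.
#' @export
locate_pixel <- function(grid, lon, lat) {
  bbox <- attr(grid, "bbox"); n_lon <- attr(grid, "n_lon")
  d_lon <- attr(grid, "d_lon"); d_lat <- attr(grid, "d_lat")
  n_lat <- attr(grid, "n_lat")
  i <- pmin(pmax(ceiling((lon - bbox[1]) / d_lon), 1L), n_lon)
  j <- pmin(pmax(ceiling((lat - bbox[3]) / d_lat), 1L), n_lat)
  as.integer((j - 1L) * n_lon + i)
}

#' Age bins used for age-stratified map products
#'
#' The stratified maps use bins (6, 24], (24, 42] and (42, 60] months;
#' since hemoglobin is only measured up to 59 months the last bin is
#' capped at 59.  Each element is the inclusive integer-month range
#' averaged over within the bin.
#'
#' @return Named list of `c(first_month, last_month)` pairs.
#' @export
default_age_bins <- function() {
  list("(6,24]" = c(7, 24), "(24,42]" = c(25, 42), "(42,60]" = c(43, 59))
}

# Split the fit's blocks into those driven by the age covariate and the
# rest; exact because terms are additive and no term mixes age with other
# covariates.
split_age_blocks <- function(fit, age_col) {
  is_age <- vapply(fit$blocks, function(b)
    age_col %in% b$term$covariates, TRUE)
  list(age = fit$blocks[is_age], other = fit$blocks[!is_age])
}

# Per-draw predictor matrices (draws x rows) for a set of blocks.
eta_for_blocks <- function(fit, blocks, newdata) {
  out <- stats::setNames(lapply(fit$params, function(p)
    matrix(0, fit$meta$n_stored, nrow(newdata))), fit$params)
  for (b in blocks) {
    Xn <- eval_block(b, newdata)
    out[[b$term$parameter]] <- out[[b$term$parameter]] +
      fit$draws[[b$term$parameter]][[b$term$name]] %*% t(Xn)
  }
  out
}

# Map-product covariate profile: training medians/modes, with
# random-intercept covariates set to an unseen level so their
# contribution is marginalized at zero.
map_profile <- function(fit) {
  prof <- fit$profile
  for (b in fit$blocks)
    if (b$term$kind == "random_intercept")
      prof[[b$term$covariates]] <- "(new)"
  prof
}

#' Pixel-level severity prevalence surface with credible intervals
#'
#' For every unmasked pixel and posterior draw, computes the probability
#' of each anemia severity class from the fitted response distribution,
#' averaging over an integer-month age grid within the requested age
#' stratum.  Geo-referenced covariates come from the grid; all other
#' covariates are fixed at the training median (numeric) or mode
#' (categorical); random intercepts are marginalized at zero.  Draws are
#' summarized by the posterior mean and the equal-tailed 95% credible
#' interval.
#'
#' @param fit An [sample_posterior()] fit.
#' @param grid A pixel grid (mask honored; masked pixels emit no
#'   estimate).
#' @param age_stratum Inclusive integer-month range `c(first, last)`
#'   within `[6, 59]`; default all ages.  See [default_age_bins()].
#' @param severity Severity classes to return (default all four).
#' @param year Optional calendar year fixed into the survey-year
#'   covariate.
#' @param thresholds A [severity_thresholds()].
#' @param age_col Name of the age covariate.
#' @param keep_draws Attach per-draw prevalence matrices (needed for
#'   admin aggregation) as attribute `"draws"`.
#' @return Long data.frame of class `prevalence_surface`: `pixel_id`,
#'   `severity`, `mean`, `lower95`, `upper95`.
#' @export
predict_prevalence_surface <- function(fit, grid,
                                       age_stratum = c(6, 59),
                                       severity = c("any", "mild",
                                                    "moderate", "severe"),
                                       year = NULL,
                                       thresholds = severity_thresholds(),
                                       age_col = "age_months",
                                       keep_draws = FALSE) {
  severity <- match.arg(severity, several.ok = TRUE)
  if (age_stratum[1] < 6 || age_stratum[2] > 59 ||
      age_stratum[1] > age_stratum[2])
    stop("age_stratum must be an increasing range within [6, 59]")
  ages <- seq.int(ceiling(age_stratum[1]), floor(age_stratum[2]))
  sub <- as.data.frame(grid)[!grid$mask_flag, , drop = FALSE]
  if (nrow(sub) == 0L) stop("all pixels are masked")

  prof <- map_profile(fit)
  needed <- unique(unlist(lapply(fit$blocks, function(b) b$term$covariates)))
  newdata <- sub
  for (cv in setdiff(needed, c(names(sub), age_col)))
    newdata[[cv]] <- prof[[cv]]
  if (!is.null(year)) newdata$survey_year <- year

  parts <- split_age_blocks(fit, age_col)
  eta_pix <- eta_for_blocks(fit, parts$other, newdata)
  age_df <- stats::setNames(data.frame(ages), age_col)
  eta_age <- eta_for_blocks(fit, parts$age, age_df)

  S <- fit$meta$n_stored
  npix <- nrow(sub)
  fam <- fit$family
  cuts <- c(any = thresholds$any, mild = thresholds$mild_lower,
            moderate = thresholds$moderate_lower)
  cdf_acc <- list(any = matrix(0, S, npix), mild = matrix(0, S, npix),
                  moderate = matrix(0, S, npix))
  sig_fix <- !("sigma" %in% fit$params)
  for (a in seq_along(ages)) {
    mu <- eta_pix$mu + eta_age$mu[, a]
    sigma <- if (sig_fix) matrix(fit$meta$fixed_sigma, S, npix)
             else exp(eta_pix$sigma + eta_age$sigma[, a])
    for (nm in names(cuts))
      cdf_acc[[nm]] <- cdf_acc[[nm]] + fam$cdf(cuts[[nm]], mu, sigma)
  }
  for (nm in names(cdf_acc)) cdf_acc[[nm]] <- cdf_acc[[nm]] / length(ages)
  prev <- list(any = cdf_acc$any,
               mild = cdf_acc$any - cdf_acc$mild,
               moderate = cdf_acc$mild - cdf_acc$moderate,
               severe = cdf_acc$moderate)

  out <- do.call(rbind, lapply(severity, function(sv) {
    sm <- summarize_draws(prev[[sv]])
    data.frame(pixel_id = sub$pixel_id, severity = sv, mean = sm$mean,
               lower95 = sm$lower, upper95 = sm$upper)
  }))
  class(out) <- c("prevalence_surface", "data.frame")
  attr(out, "age_stratum") <- age_stratum
  if (keep_draws) {
    for (sv in names(prev)) colnames(prev[[sv]]) <- sub$pixel_id
    attr(out, "draws") <- prev[severity]
  }
  out
}

#' Marginal prevalence curve at a location (20-km buffer rule)
#'
#' Prevalence of a severity class as one focal covariate varies, with all
#' other covariates fixed at the median (numeric) or mode (categorical)
#' observed among survey records within a great-circle buffer (default
#' 20 km) around the location.  Reports the posterior mean curve with the
#' equal-tailed 95% credible band and the buffer median of the focal
#' covariate (the dashed reference line of the marginal-effect figures).
#'
#' @param fit An [sample_posterior()] fit.
#' @param survey Survey data.frame (supplies the buffer profile).
#' @param lon,lat Location, degrees WGS84.
#' @param covariate Focal covariate name.
#' @param grid_values Evaluation grid; defaults to 50 points over the
#'   survey range of the focal covariate.
#' @param buffer_km Buffer radius, km (> 0).
#' @param severity Severity class of the reported prevalence.
#' @param thresholds A [severity_thresholds()].
#' @return List of class `marginal_curve`: `curve` (data.frame `value`,
#'   `mean`, `lower95`, `upper95`), `focal_median`, `n_buffer`.
#' @export
marginal_curve <- function(fit, survey, lon, lat, covariate,
                           grid_values = NULL, buffer_km = 20,
                           severity = "any",
                           thresholds = severity_thresholds()) {
  if (buffer_km <= 0) stop("buffer_km must be positive")
  severity <- match.arg(severity, c("any", "mild", "moderate", "severe"))
  d <- distance_km(survey$lon, survey$lat, lon, lat)
  inside <- d <= buffer_km
  if (!any(inside))
    stop(sprintf("no survey records within %g km of (%g, %g)",
                 buffer_km, lon, lat))
  buf <- survey[inside, , drop = FALSE]
  prof <- typical_profile(buf, names(buf))
  for (b in fit$blocks)                     # marginalize random intercepts
    if (b$term$kind == "random_intercept")
      prof[[b$term$covariates]] <- "(new)"
  prof$lon <- lon; prof$lat <- lat
  if (is.null(grid_values)) {
    v <- survey[[covariate]]
    grid_values <- if (is.numeric(v))
      seq(min(v), max(v), length.out = 50) else sort(unique(v))
  }
  newdata <- as.data.frame(prof[!vapply(prof, is.null, TRUE)],
                           stringsAsFactors = FALSE)
  newdata <- newdata[rep(1L, length(grid_values)), , drop = FALSE]
  newdata[[covariate]] <- grid_values
  pred <- predict_parameters(fit, newdata)
  pcol <- paste0("p_", severity)
  pm <- matrix(0, nrow(pred$mu), ncol(pred$mu))
  for (s in seq_len(nrow(pred$mu)))
    pm[s, ] <- severity_probabilities(pred$mu[s, ], pred$sigma[s, ],
                                      thresholds, fit$family)[[pcol]]
  sm <- summarize_draws(pm)
  structure(list(curve = data.frame(value = grid_values, mean = sm$mean,
                                    lower95 = sm$lower, upper95 = sm$upper),
                 focal_median = if (is.numeric(buf[[covariate]]))
                   stats::median(buf[[covariate]]) else stat_mode(buf[[covariate]]),
                 n_buffer = sum(inside), severity = severity,
                 covariate = covariate),
            class = "marginal_curve")
}

#' Write a prevalence surface to CSV
#' @param surface A `prevalence_surface`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_surface_csv <- function(surface, path) {
  utils::write.csv(as.data.frame(surface), path, row.names = FALSE)
  invisible(path)
}
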