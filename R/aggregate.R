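#' Population-weighted aggregation of pixel prevalence draws
#'
#' Aggregates per-draw pixel prevalences to administrative units as the
#' population-weighted mean, computed *per posterior draw* and only then
#' summarized -- so credible intervals propagate the full posterior
#' uncertainty instead of averaging interval endpoints.
#'
#' @param pixel_draws Matrix of prevalence draws (draws x pixels); column
#'   names must be pixel ids (as produced by
#'   [predict_prevalence_surface()] with `keep_draws = TRUE`).
#' @param grid Pixel grid carrying `pixel_id` and `population`.
#' @param admin Admin partition (data.frame `pixel_id`, `country`,
#'   `admin1_id`, `admin2_id`, see [make_admin_partition()]).
#' @param level Aggregation level: `"admin2"`, `"admin1"` or `"country"`.
#' @return Object of class `admin_estimate`: list with `summary`
#'   (data.frame `admin_id`, `level`, `mean`, `lower95`, `upper95`,
#'   `population`) and `draws` (draws x units matrix).  Units with zero
#'   total population are skipped with a warning.
#' @export
aggregate_admin <- function(pixel_draws, grid, admin,
                            level = c("admin2", "admin1", "country")) {
  level <- match.arg(level)
  stopifnot(is.matrix(pixel_draws))
  ids <- as.integer(colnames(pixel_draws))
  if (anyNA(ids)) stop("pixel_draws must carry pixel ids as column names")
  gi <- match(ids, grid$pixel_id)
  if (anyNA(gi)) stop("pixel_draws contain pixels absent from the grid")
  ai <- match(ids, admin$pixel_id)
  if (anyNA(ai)) stop("every unmasked pixel must be assigned to an admin unit")
  unit <- switch(level, admin2 = admin$admin2_id[ai],
                 admin1 = admin$admin1_id[ai], country = admin$country[ai])
  popn <- grid$population[gi]
  units <- sort(unique(unit))
  keep <- vapply(units, function(u) sum(popn[unit == u]) > 0, TRUE)
  if (any(!keep))
    warning("skipping admin unit(s) with zero population: ",
            paste(units[!keep], collapse = ", "))
  units <- units[keep]
  W <- vapply(units, function(u) {
    w <- ifelse(unit == u, popn, 0)
    w / sum(w)
  }, numeric(length(popn)))
  draws <- pixel_draws %*% W
  colnames(draws) <- units
  sm <- summarize_draws(draws)
  structure(list(summary = data.frame(admin_id = units, level = level,
                                      mean = sm$mean, lower95 = sm$lower,
                                      upper95 = sm$upper,
                                      population = vapply(units, function(u)
                                        sum(popn[unit == u]), 0)),
                 draws = draws, level = level),
            class = "admin_estimate")
}

#' Affected-children counts from prevalence draws
#'
#' Multiplies per-draw prevalence by the population at risk and
#' summarizes with an equal-tailed 95% interval.
#'
#' @param prev_draws Prevalence draws: a vector (one unit) or a draws x
#'   units matrix (e.g. `$draws` of an [aggregate_admin()] result).
#' @param population Population at risk per unit (>= 0), recycled.
#' @return Data.frame `mean`, `lower95`, `upper95` (one row per unit)
#'   with the per-draw counts attached as attribute `"draws"`.
#' @export
affected_children <- function(prev_draws, population) {
  if (any(population < 0)) stop("population must be >= 0")
  if (!is.matrix(prev_draws)) prev_draws <- matrix(prev_draws, ncol = 1L)
  counts <- sweep(prev_draws, 2L, population, `*`)
  sm <- summarize_draws(counts)
  structure(data.frame(mean = sm$mean, lower95 = sm$lower,
                       upper95 = sm$upper), draws = counts)
}

#' Classify a prevalence trend between two years
#'
#' Change classification on percentage points: a decrease of more than 2
#' points, an increase of more than 2 points, or "more or less constant"
#' within the symmetric band (-2, +2).
#'
#' @param p_start,p_end Prevalence at the start and end year, in percent
#'   (`[0, 100]`); vectorized.
#' @param band Half-width of the constant band, percentage points.
#' @return Factor with levels `decrease`, `constant`, `increase`.
#' @examples
#' classify_trend(87.3, 77.1)  # decrease
#' classify_trend(71.9, 72.7)  # constant
#' @export
classify_trend <- function(p_start, p_end, band = 2) {
  if (any(p_start < 0 | p_start > 100 | p_end < 0 | p_end > 100))
    stop("prevalences must be percentages in [0, 100]")
  delta <- p_end - p_start
  factor(ifelse(delta < -band, "decrease",
                ifelse(delta > band, "increase", "constant")),
         levels = c("decrease", "constant", "increase"))
}

#' Within-country inequality summary at admin-2 level
#'
#' The spread of admin-2 posterior-mean prevalences within one country:
#' the lowest and highest admin-2 estimate, their range, and the country
#' estimate (which need not lie between them only in pathological
#' weighting cases; min <= max always).
#'
#' @param admin2_means Numeric vector of admin-2 posterior means (>= 1).
#' @param country_mean Country-level posterior mean.
#' @return List `min`, `max`, `range`, `country`.
#' @export
inequality_summary <- function(admin2_means, country_mean) {
  if (length(admin2_means) == 0L) stop("need at least one admin-2 estimate")
  list(min = min(admin2_means), max = max(admin2_means),
       range = max(admin2_means) - min(admin2_means),
       country = country_mean)
}

#' @export
print.admin_estimate <- function(x, ...) {
  cat("population-weighted", x$level, "prevalence estimates\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
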