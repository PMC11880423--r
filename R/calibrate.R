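#' Train/test split of a survey
#'
#' Splits the survey into a training part (default 80%) and a held-out
#' test part used for validation only.  With `unit = "cluster"` (the
#' default) whole primary sampling units are assigned to one side, so no
#' cluster contributes to both partitions and spatial leakage between
#' train and test is avoided; `unit = "record"` splits child records
#' directly.
#'
#' @param data Survey data.frame.
#' @param train_fraction Fraction of units in the training part, in
#'   (0, 1).
#' @param unit `"cluster"` or `"record"`.
#' @param seed Integer seed; the same seed reproduces the split.
#' @param cluster_col Cluster id column.
#' @return List with data.frames `train` and `test`.
#' @export
split_data <- function(data, train_fraction = 0.8,
                       unit = c("cluster", "record"), seed = 1L,
                       cluster_col = "cluster_id") {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  unit <- match.arg(unit)
  if (unit == "record") {
    n <- nrow(data)
    n_train <- round(train_fraction * n)
    if (n_train == 0L || n_train == n)
      stop("both partitions must be non-empty")
    idx <- with_seed(seed, sample.int(n, n_train))
    train <- data[sort(idx), , drop = FALSE]
    test <- data[-sort(idx), , drop = FALSE]
  } else {
    cl <- unique(data[[cluster_col]])
    k <- round(train_fraction * length(cl))
    if (k == 0L || k == length(cl))
      stop("both partitions must be non-empty")
    tr_cl <- with_seed(seed, sample(cl, k))
    train <- data[data[[cluster_col]] %in% tr_cl, , drop = FALSE]
    test <- data[!data[[cluster_col]] %in% tr_cl, , drop = FALSE]
  }
  list(train = train, test = test)
}

#' Probability integral transform of held-out observations
#'
#' For each test record, evaluates the posterior predictive CDF (the
#' mixture over parameter draws) at the observed value.  For a calibrated
#' model the transforms are Uniform(0, 1): the 10-bin histogram is flat,
#' and both the Kolmogorov-Smirnov distance and a chi-square test against
#' uniformity quantify departures (underdispersed predictives produce the
#' characteristic U shape).
#'
#' @param y Observed held-out responses.
#' @param pred An `anemap_pred` for the same records (see
#'   [predict_parameters()] / [param_draws()]).
#' @param bins Number of equal-width histogram bins.
#' @return List of class `calibration_pit`: `u` (PIT values in `[0, 1]`),
#'   `histogram` (bin counts), `breaks`, `ks_statistic`, `ks_p`,
#'   `chisq_statistic`, `chisq_p`.
#' @export
pit <- function(y, pred, bins = 10) {
  stopifnot(length(y) > 0)
  u <- predictive_cdf(pred, y)
  breaks <- seq(0, 1, length.out = bins + 1L)
  counts <- as.integer(table(cut(u, breaks, include.lowest = TRUE)))
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  chi <- suppressWarnings(stats::chisq.test(counts))
  structure(list(u = u, histogram = counts, breaks = breaks,
                 ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
                 chisq_statistic = unname(chi$statistic),
                 chisq_p = chi$p.value),
            class = "calibration_pit")
}

#' Out-of-sample posterior prediction interval coverage
#'
#' Fraction of held-out observations that fall inside their equal-tailed
#' posterior prediction interval at the given level.  For a model with
#' good predictive properties approximately 95% of held-out values lie
#' within the 95% interval.
#'
#' @param y Observed held-out responses.
#' @param pred An `anemap_pred` for the same records.
#' @param level Interval level in (0, 1].
#' @return Covered fraction in `[0, 1]`.
#' @export
ppi_coverage <- function(y, pred, level = 0.95) {
  if (level <= 0 || level > 1) stop("level must be in (0, 1]")
  if (level == 1) return(1)
  u <- predictive_cdf(pred, y)
  alpha <- (1 - level) / 2
  mean(u >= alpha & u <= 1 - alpha)
}

#' Validation of model-based admin-2 estimates against direct estimates
#'
#' Pearson correlation between the model-based prevalence aggregated to
#' admin-2 units and the direct survey estimate (pooled proportion of
#' classified records) for the same units.
#'
#' @param model_est Named numeric vector of model-based admin-2
#'   prevalences (names are admin-2 ids).
#' @param direct_est Named numeric vector of direct estimates.
#' @return List `rho`, `n_units`, `table` (data.frame `admin_id`,
#'   `model`, `direct`).  Requires at least 3 common units.
#' @export
admin2_validation <- function(model_est, direct_est) {
  common <- intersect(names(model_est), names(direct_est))
  if (length(common) < 3)
    stop("need at least 3 admin-2 units with both estimates")
  tab <- data.frame(admin_id = common,
                    model = as.numeric(model_est[common]),
                    direct = as.numeric(direct_est[common]))
  list(rho = stats::cor(tab$model, tab$direct), n_units = nrow(tab),
       table = tab)
}

#' Direct (survey-based) admin-2 severity prevalence
#'
#' Design-naive direct estimates: each record is classified by its
#' hemoglobin level and records are pooled within the admin-2 unit of the
#' pixel containing their cluster location.
#'
#' @param survey Survey data.frame with `hb`, `lon`, `lat`.
#' @param grid The pixel grid the admin partition refers to.
#' @param admin Admin partition data.frame.
#' @param severity Severity class (`"any"`, `"mild"`, `"moderate"`,
#'   `"severe"`).
#' @param thresholds A [severity_thresholds()].
#' @return Named numeric vector of prevalences per admin-2 id.
#' @export
direct_admin2_estimates <- function(survey, grid, admin, severity = "any",
                                    thresholds = severity_thresholds()) {
  severity <- match.arg(severity, c("any", "mild", "moderate", "severe"))
  pid <- locate_pixel(grid, survey$lon, survey$lat)
  a2 <- admin$admin2_id[match(pid, admin$pixel_id)]
  cls <- classify_severity(survey$hb, thresholds)
  hit <- if (severity == "any") cls != "none" else cls == severity
  tapply(hit, a2, mean)
}
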