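#' Response families for location-scale hemoglobin models
#'
#' A family object bundles everything the boosting and MCMC engines need to
#' know about the response distribution: the log-likelihood, per-observation
#' scores and expected working weights with respect to each predictor, the
#' CDF/quantile pair used for severity probabilities and calibration, and a
#' reproducible random generator.  Both distribution parameters carry their
#' own structured additive predictor: the location `mu` uses an identity
#' link, the scale `sigma` a log link, so any real-valued predictor maps to
#' a valid parameter pair.
#'
#' `gaussian_ls()` is the default Normal location-scale family used for
#' hemoglobin (g/L).  `student_ls()` is a fixed-shape Student-t alternative
#' demonstrating that the engine is family-agnostic; it is not a default.
#'
#' @param df Degrees of freedom (> 2) for the Student-t family.
#' @return An object of class `anemap_family`: a list with elements
#'   `name`, `params` (`c("mu", "sigma")`), `links`, `loglik(y, mu, sigma)`,
#'   `score(y, mu, sigma, which)`, `weight(y, mu, sigma, which)` (scores and
#'   expected information are with respect to the *predictor* of `which`),
#'   `cdf`, `quantile`, `rng(n, mu, sigma, seed)` and `conjugate` (logical
#'   per parameter: does the predictor have an exact Gaussian full
#'   conditional given the other parameter?).
#' @examples
#' fam <- gaussian_ls()
#' fam$loglik(110, 110, 1)        # log density at the mean
#' fam$cdf(110, 110, 10)          # 0.5
#' @export
gaussian_ls <- function() {
  check <- function(y, mu, sigma) {
    if (any(!is.finite(y))) stop("non-finite response values")
    if (any(sigma <= 0)) stop("sigma must be positive")
  }
  structure(list(
    name = "gaussian",
    params = c("mu", "sigma"),
    links = c(mu = "identity", sigma = "log"),
    conjugate = c(mu = TRUE, sigma = FALSE),
    loglik = function(y, mu, sigma) {
      check(y, mu, sigma)
      sum(stats::dnorm(y, mu, sigma, log = TRUE))
    },
    score = function(y, mu, sigma, which = c("mu", "sigma")) {
      check(y, mu, sigma)
      which <- match.arg(which)
      r <- (y - mu) / sigma
      if (which == "mu") r / sigma else r^2 - 1
    },
    weight = function(y, mu, sigma, which = c("mu", "sigma")) {
      which <- match.arg(which)
      if (which == "mu") 1 / sigma^2 else rep(2, length(y))
    },
    cdf = function(y, mu, sigma) {
      if (any(sigma <= 0)) stop("sigma must be positive")
      stats::pnorm(y, mu, sigma)
    },
    quantile = function(p, mu, sigma) stats::qnorm(p, mu, sigma),
    rng = function(n, mu, sigma, seed = NULL) {
      if (any(sigma <= 0)) stop("sigma must be positive")
      with_seed(seed, stats::rnorm(n, mu, sigma))
    }
  ), class = "anemap_family")
}

#' @rdname gaussian_ls
#' @export
student_ls <- function(df = 5) {
  stopifnot(df > 2)
  check <- function(y, mu, sigma) {
    if (any(!is.finite(y))) stop("non-finite response values")
    if (any(sigma <= 0)) stop("sigma must be positive")
  }
  structure(list(
    name = sprintf("student(df=%g)", df),
    params = c("mu", "sigma"),
    links = c(mu = "identity", sigma = "log"),
    conjugate = c(mu = FALSE, sigma = FALSE),
    loglik = function(y, mu, sigma) {
      check(y, mu, sigma)
      sum(stats::dt((y - mu) / sigma, df, log = TRUE) - log(sigma))
    },
    score = function(y, mu, sigma, which = c("mu", "sigma")) {
      check(y, mu, sigma)
      which <- match.arg(which)
      z <- (y - mu) / sigma
      w <- (df + 1) / (df + z^2)
      if (which == "mu") w * z / sigma else w * z^2 - 1
    },
    weight = function(y, mu, sigma, which = c("mu", "sigma")) {
      which <- match.arg(which)
      if (which == "mu") (df + 1) / ((df + 3) * sigma^2)
      else rep(2 * df / (df + 3), length(y))
    },
    cdf = function(y, mu, sigma) {
      if (any(sigma <= 0)) stop("sigma must be positive")
      stats::pt((y - mu) / sigma, df)
    },
    quantile = function(p, mu, sigma) mu + sigma * stats::qt(p, df),
    rng = function(n, mu, sigma, seed = NULL) {
      if (any(sigma <= 0)) stop("sigma must be positive")
      with_seed(seed, mu + sigma * stats::rt(n, df))
    }
  ), class = "anemap_family")
}

#' @export
print.anemap_family <- function(x, ...) {
  cat("anemap location-scale family:", x$name, "\n")
  cat("links: mu =", x$links[["mu"]], ", sigma =", x$links[["sigma"]], "\n")
  invisible(x)
}
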