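#' Noncyclic gradient boosting for location-scale term selection
#'
#' Componentwise gradient boosting over candidate structured additive
#' terms of *both* distribution parameters jointly.  At each iteration
#' every candidate block is fitted by penalized least squares to the
#' current working gradient of its parameter; the single block (across mu
#' and sigma) whose damped update most improves the training
#' log-likelihood is updated by `step` times its fit.  Selection
#' frequencies -- the fraction of iterations in which each term was the
#' updated block -- are the variable-importance measure used to choose the
#' terms passed on to the MCMC stage.
#'
#' Penalized base learners are kept weak and mutually comparable by fixing
#' their effective degrees of freedom (default 4).  Intercepts are not
#' candidates: they are fitted once as offsets (the family's location and
#' log-scale of the response) and always retained.  Ties in improvement
#' are broken by the fixed candidate order, so the procedure is fully
#' deterministic; iteration stops early if no candidate improves the
#' likelihood.
#'
#' @param data Survey data.frame.
#' @param terms Candidate terms (list of [term_spec()]s, e.g. from
#'   [parse_terms()]); intercept terms may be included and are treated as
#'   offsets.
#' @param family An `anemap_family`.
#' @param n_iter Iteration budget (>= 0).
#' @param step Learning rate in (0, 1].
#' @param edf Effective-degrees-of-freedom target of penalized base
#'   learners.
#' @param y_col Response column name.
#' @return A list of class `boost_result`: `selection_frequency`
#'   (data.frame parameter/term/frequency/n_updates), `coefficient_paths`
#'   (per-iteration cumulative coefficients, one matrix per block),
#'   `loglik_path` (non-decreasing), `n_iter_run`, `terms`, `offsets`.
#' @export
boost_select <- function(data, terms, family = gaussian_ls(),
                         n_iter = 200, step = 0.1, edf = 4,
                         y_col = "hb") {
  if (n_iter < 0) stop("n_iter must be >= 0")
  if (step <= 0 || step > 1) stop("step must be in (0, 1]")
  y <- data[[y_col]]
  if (is.null(y)) stop("response column '", y_col, "' not found")
  design <- build_design(data, terms)
  params <- names(design)
  if (!all(params %in% family$params))
    stop("terms reference parameters outside the family contract")

  cand <- list()
  for (p in params) for (blk in design[[p]]) {
    if (blk$term$kind == "intercept") next
    cand[[length(cand) + 1L]] <- prep_learner(blk, edf)
  }
  if (length(cand) == 0L) stop("no candidate terms to select from")

  # offsets: family-typical location and log-scale of the response
  eta <- list(mu = rep(mean(y), length(y)),
              sigma = rep(log(stats::sd(y)), length(y)))
  coefs <- lapply(cand, function(cl) numeric(ncol(cl$X)))
  paths <- lapply(cand, function(cl)
    matrix(0, 0, ncol(cl$X)))
  counts <- integer(length(cand))
  ll <- family$loglik(y, eta$mu, exp(eta$sigma))
  ll_path <- numeric(0)
  n_done <- 0L

  for (it in seq_len(n_iter)) {
    mu <- eta$mu; sigma <- exp(eta$sigma)
    # working gradient (score over expected information): Fisher-scoring
    # boosting keeps update magnitudes on the predictor scale for every
    # parameter
    grad <- lapply(stats::setNames(nm = c("mu", "sigma")), function(p)
      family$score(y, mu, sigma, p) / family$weight(y, mu, sigma, p))
    best <- 0L; best_ll <- ll; best_b <- NULL
    for (j in seq_along(cand)) {
      cl <- cand[[j]]
      b <- backsolve(cl$R, forwardsolve(t(cl$R), crossprod(cl$X, grad[[cl$param]])))
      eta_new <- eta[[cl$param]] + step * as.numeric(cl$X %*% b)
      ll_new <- if (cl$param == "mu") family$loglik(y, eta_new, sigma)
                else family$loglik(y, mu, exp(eta_new))
      if (ll_new > best_ll + 1e-12) { best <- j; best_ll <- ll_new; best_b <- b }
    }
    if (best == 0L) break
    cl <- cand[[best]]
    eta[[cl$param]] <- eta[[cl$param]] + step * as.numeric(cl$X %*% best_b)
    coefs[[best]] <- coefs[[best]] + step * as.numeric(best_b)
    counts[best] <- counts[best] + 1L
    ll <- best_ll
    n_done <- it
    ll_path <- c(ll_path, ll)
    paths <- lapply(seq_along(paths), function(j)
      rbind(paths[[j]], coefs[[j]]))
  }

  freq <- data.frame(
    parameter = vapply(cand, function(cl) cl$param, ""),
    term = vapply(cand, function(cl) cl$term$name, ""),
    frequency = if (n_done > 0) counts / n_done else rep(0, length(cand)),
    n_updates = counts)
  names(paths) <- paste0(freq$parameter, ":", freq$term)
  structure(list(selection_frequency = freq,
                 coefficient_paths = paths,
                 loglik_path = ll_path,
                 n_iter_run = n_done,
                 n_iter_budget = n_iter,
                 terms = terms,
                 offsets = c(mu = mean(y), sigma = log(stats::sd(y)))),
            class = "boost_result")
}

# Precompute the penalized-least-squares factor of one base learner.  The
# smoothing parameter is chosen so the learner has the target effective
# degrees of freedom; unpenalized learners use lambda = 0.
prep_learner <- function(blk, edf) {
  X <- blk$XZ
  G <- crossprod(X)
  if (is.null(blk$K) || ncol(X) <= edf) {
    A <- G + diag(1e-8 * max(diag(G)), ncol(X))
  } else {
    K <- blk$KZ
    tr_edf <- function(loglam) {
      M <- G + exp(loglam) * K
      sum(diag(solve(M, G)))
    }
    lo <- -15; hi <- 25
    lam <- tryCatch(
      exp(stats::uniroot(function(l) tr_edf(l) - edf, c(lo, hi))$root),
      error = function(e) 1)   # fall back to unit smoothing if bracketing fails
    A <- G + lam * K + diag(1e-10 * max(diag(G)), ncol(X))
  }
  list(X = X, R = chol(A), param = blk$term$parameter, term = blk$term)
}

#' Threshold boosting selection frequencies into a reduced term set
#'
#' Deterministic thresholding: a term survives when its selection
#' frequency is positive and at least `frequency_floor`.  Intercepts are
#' always retained for every parameter present in the candidate set.
#'
#' @param result A [boost_select()] result.
#' @param frequency_floor Frequency threshold in `[0, 1]` (default 0.05).
#' @return A list with `selected` (character vector of surviving
#'   parameter:term labels) and `terms` (the corresponding `term_spec`
#'   list including intercepts, ready for [sample_posterior()]).
#' @export
select_terms <- function(result, frequency_floor = 0.05) {
  stopifnot(inherits(result, "boost_result"))
  if (frequency_floor < 0 || frequency_floor > 1)
    stop("frequency_floor must be in [0, 1]")
  fr <- result$selection_frequency
  keep <- fr$frequency > 0 & fr$frequency >= frequency_floor
  lab <- paste0(fr$parameter, ":", fr$term)[keep]
  terms <- Filter(function(t) {
    t$kind == "intercept" || paste0(t$parameter, ":", t$name) %in% lab
  }, result$terms)
  list(selected = lab, terms = terms)
}

#' @export
print.boost_result <- function(x, ...) {
  cat("noncyclic boosting:", x$n_iter_run, "of", x$n_iter_budget,
      "iterations run\n")
  fr <- x$selection_frequency
  print(fr[order(-fr$frequency), ], row.names = FALSE)
  invisible(x)
}
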