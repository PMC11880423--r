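#' Structured additive term specification
#'
#' A `term_spec` describes one component of a structured additive predictor:
#' a linear term, a penalized B-spline (P-spline), a spatial tensor-product
#' surface over longitude/latitude, a cluster random intercept, or the
#' intercept itself.  Defaults follow standard P-spline practice: cubic
#' B-splines with 20 basis functions and a second-order difference penalty
#' for univariate smooths, 10 basis functions per margin for the spatial
#' tensor.
#'
#' @param kind One of `"intercept"`, `"linear"`, `"pspline"`,
#'   `"spatial_tensor"`, `"random_intercept"`.
#' @param covariates Character vector of covariate names (two for the
#'   spatial tensor: longitude then latitude).
#' @param parameter Which distribution parameter the term belongs to
#'   (`"mu"` or `"sigma"`).
#' @param n_basis Number of basis functions (per margin for tensors).
#' @param degree B-spline degree; must be `< n_basis`.
#' @param penalty_order Difference-penalty order (>= 1 for penalized kinds).
#' @param name Optional label; autogenerated from kind and covariates.
#' @return A list of class `term_spec`.
#' @seealso [parse_terms()] for the formula-string interface.
#' @export
term_spec <- function(kind, covariates = character(), parameter = "mu",
                      n_basis = NULL, degree = 3, penalty_order = 2,
                      name = NULL) {
  kind <- match.arg(kind, c("intercept", "linear", "pspline",
                            "spatial_tensor", "random_intercept"))
  parameter <- match.arg(parameter, c("mu", "sigma"))
  if (kind %in% c("linear", "pspline", "random_intercept") &&
      length(covariates) != 1L)
    stop(kind, " terms take exactly one covariate")
  if (kind == "spatial_tensor" && length(covariates) != 2L)
    stop("spatial_tensor terms take two covariates (lon, lat)")
  if (is.null(n_basis))
    n_basis <- switch(kind, pspline = 20L, spatial_tensor = 10L, 0L)
  if (kind %in% c("pspline", "spatial_tensor")) {
    if (n_basis <= degree) stop("n_basis must exceed the spline degree")
    if (penalty_order < 1) stop("penalty_order must be >= 1")
    if (penalty_order >= n_basis) stop("penalty_order must be < n_basis")
  }
  if (is.null(name)) {
    name <- switch(kind,
      intercept = "1",
      linear = sprintf("linear(%s)", covariates),
      pspline = sprintf("s(%s)", covariates),
      spatial_tensor = sprintf("te(%s,%s)", covariates[1L], covariates[2L]),
      random_intercept = sprintf("ri(%s)", covariates))
  }
  structure(list(name = name, kind = kind, covariates = covariates,
                 parameter = parameter, n_basis = as.integer(n_basis),
                 degree = as.integer(degree),
                 penalty_order = as.integer(penalty_order)),
            class = "term_spec")
}

#' Parse a formula-like model string into term specifications
#'
#' Accepts strings such as
#' `"mu ~ 1 + linear(wealth_index) + s(age_months, k = 20) + te(lon, lat)"`
#' and `"sigma ~ 1 + linear(elevation)"`.  Recognized constructors are `1`
#' (intercept), `linear(x)`, `s(x, k = )` (P-spline), `te(lon, lat, k = )`
#' (spatial tensor) and `ri(id)` (random intercept).
#'
#' @param ... One formula string per distribution parameter.
#' @return A list of `term_spec` objects.
#' @examples
#' parse_terms("mu ~ 1 + s(age_months) + linear(wealth_index)",
#'             "sigma ~ 1 + linear(elevation)")
#' @export
parse_terms <- function(...) {
  out <- list()
  for (fml in unlist(list(...))) {
    parts <- strsplit(fml, "~", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("expected '<parameter> ~ terms': ", fml)
    param <- trimws(parts[1L])
    for (tok in trimws(strsplit(parts[2L], "+", fixed = TRUE)[[1L]])) {
      if (tok == "") next
      out[[length(out) + 1L]] <- parse_one_term(tok, param)
    }
  }
  out
}

parse_one_term <- function(tok, param) {
  if (tok == "1") return(term_spec("intercept", parameter = param))
  m <- regmatches(tok, regexec("^([a-z_]+)\\(([^)]*)\\)$", tok))[[1L]]
  if (length(m) != 3L) stop("cannot parse term '", tok, "'")
  fn <- m[2L]
  args <- trimws(strsplit(m[3L], ",", fixed = TRUE)[[1L]])
  kset <- grepl("^k\\s*=", args)
  k <- if (any(kset)) as.integer(sub("^k\\s*=\\s*", "", args[kset])) else NULL
  vars <- args[!kset]
  switch(fn,
    linear = term_spec("linear", vars, param),
    s = term_spec("pspline", vars, param, n_basis = k %||% 20L),
    te = term_spec("spatial_tensor", vars, param, n_basis = k %||% 10L),
    ri = term_spec("random_intercept", vars, param),
    stop("unknown term constructor '", fn, "'"))
}

#' Format term specifications back into formula strings
#' @param terms List of `term_spec` objects.
#' @return Named character vector, one formula string per parameter.
#' @export
format_terms <- function(terms) {
  params <- unique(vapply(terms, `[[`, "", "parameter"))
  vapply(params, function(p) {
    nm <- vapply(terms[vapply(terms, `[[`, "", "parameter") == p],
                 `[[`, "", "name")
    paste(p, "~", paste(nm, collapse = " + "))
  }, "")
}

#' B-spline basis with equally spaced knots
#'
#' Evaluates `n_basis` B-spline basis functions of the given degree at `x`,
#' with equally spaced knots spanning `[min(x), max(x)]` plus the usual
#' boundary extension.  Within the knot range rows form a partition of
#' unity.  When `knots` (as stored from a training call) are supplied,
#' values outside the training range are clamped to the boundary with a
#' warning; polynomial tails are never extrapolated.
#'
#' @param x Numeric vector; finite.
#' @param n_basis Number of basis functions; must exceed `degree`.
#' @param degree Spline degree (0 gives one-hot bin indicators).
#' @param knots Optional full knot vector from a previous call (attribute
#'   `"knots"` of the returned matrix).
#' @return Matrix `length(x) x n_basis` with attributes `knots` and
#'   `degree`.
#' @export
bspline_basis <- function(x, n_basis, degree = 3, knots = NULL) {
  if (any(!is.finite(x))) stop("x must be finite")
  n_basis <- as.integer(n_basis)
  if (n_basis <= degree) stop("n_basis must exceed the spline degree")
  if (is.null(knots)) {
    lo <- min(x); hi <- max(x)
    if (hi <= lo) { lo <- lo - 0.5; hi <- hi + 0.5 }
    n_break <- n_basis - degree + 1L
    h <- (hi - lo) / (n_break - 1L)
    knots <- seq(lo - degree * h, hi + degree * h, by = h)
    # guard against round-off excluding the right boundary point
    knots[length(knots)] <- knots[length(knots)] + 1e-8 * max(1, abs(hi))
  }
  ord <- degree + 1L
  lo <- knots[ord]
  hi <- knots[length(knots) - ord + 1L]
  n_out <- sum(x < lo | x > hi)
  if (n_out > 0) {
    warning(sprintf("%d value(s) outside the training range clamped to [%g, %g]",
                    n_out, lo, hi))
    x <- pmin(pmax(x, lo), hi)
  }
  # evaluate just inside the right boundary so the closed-interval limit is
  # returned (B-splines are right-continuous)
  eps <- 1e-9 * max(1, abs(hi))
  B <- splines::splineDesign(knots, pmin(x, hi - eps), ord = ord,
                             outer.ok = FALSE)
  structure(B, knots = knots, degree = degree)
}

#' Difference penalty matrix for P-splines
#'
#' Returns `K = t(D) %*% D` with `D` the order-th difference operator on
#' `n_basis` coefficients.  `K` is symmetric positive semidefinite with
#' rank `n_basis - order`; its null space contains polynomial coefficient
#' sequences of degree `< order`.
#'
#' @param n_basis Number of coefficients.
#' @param order Difference order; must be `< n_basis`.
#' @return `n_basis x n_basis` penalty matrix.
#' @export
difference_penalty <- function(n_basis, order = 2) {
  n_basis <- as.integer(n_basis); order <- as.integer(order)
  if (order >= n_basis) stop("penalty order must be < n_basis")
  if (order < 1) stop("penalty order must be >= 1")
  D <- diff(diag(n_basis), differences = order)
  crossprod(D)
}

#' Tensor-product spatial basis over longitude and latitude
#'
#' Row-wise Kronecker product of marginal B-spline bases in longitude and
#' latitude, with the standard additive tensor penalty
#' `K = K_lon %x% I + I %x% K_lat`.  Rows sum to one (product of two
#' partitions of unity); a constant surface lies in the penalty null space.
#'
#' @param lon,lat Coordinate vectors of equal length (degrees).
#' @param n_basis Basis functions per margin.
#' @param degree Marginal spline degree.
#' @param penalty_order Marginal difference-penalty order.
#' @param knots Optional list with elements `lon` and `lat` (stored knot
#'   vectors from a training call).
#' @return List with `X` (basis matrix, `n x n_basis^2`), `K` (penalty),
#'   and `knots` (list of marginal knot vectors).
#' @export
tensor_spatial_basis <- function(lon, lat, n_basis = 10, degree = 3,
                                 penalty_order = 2, knots = NULL) {
  if (length(lon) != length(lat)) stop("lon and lat lengths differ")
  B1 <- bspline_basis(lon, n_basis, degree, knots = knots$lon)
  B2 <- bspline_basis(lat, n_basis, degree, knots = knots$lat)
  k1 <- ncol(B1); k2 <- ncol(B2)
  # row-wise Kronecker: column (j-1)*k2 + l is B1[, j] * B2[, l]
  X <- B1[, rep(seq_len(k1), each = k2), drop = FALSE] *
       B2[, rep(seq_len(k2), times = k1), drop = FALSE]
  K1 <- difference_penalty(k1, penalty_order)
  K2 <- difference_penalty(k2, penalty_order)
  K <- K1 %x% diag(k2) + diag(k1) %x% K2
  list(X = X, K = K,
       knots = list(lon = attr(B1, "knots"), lat = attr(B2, "knots")))
}

# Sum-to-zero constraint: Z spans the null space of colSums(X), so that
# X %*% Z %*% b has zero training-sample sum for every b.  Keeps smooth
# terms identifiable next to the intercept.
constraint_null <- function(X) {
  C <- matrix(colSums(X), nrow = 1L)
  qr.Q(qr(t(C)), complete = TRUE)[, -1L, drop = FALSE]
}

# Numerical rank via eigenvalues (symmetric PSD input).
psd_rank <- function(K, tol = 1e-8) {
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  sum(ev > tol * max(ev, 1))
}

#' Build design blocks from data and term specifications
#'
#' Turns a list of [term_spec()]s into per-parameter lists of design
#' blocks.  Each block carries the raw basis matrix `X`, the penalty `K`
#' (or `NULL` for unpenalized terms), a sum-to-zero constraint matrix `Z`
#' for smooth terms (identity for the rest), the constrained design
#' `XZ = X %*% Z`, the constrained penalty and its rank, and everything
#' needed to rebuild the basis at new data (knots, factor levels).
#' Blocks are ordered as given, intercept terms first.
#'
#' @param data A data.frame containing every referenced covariate.
#' @param terms List of `term_spec` objects (see [parse_terms()]).
#' @return A list with one element per distribution parameter (e.g. `mu`,
#'   `sigma`), each a list of blocks; class `anemap_design`.
#' @export
build_design <- function(data, terms) {
  stopifnot(is.data.frame(data), length(terms) > 0)
  params <- unique(vapply(terms, `[[`, "", "parameter"))
  out <- lapply(params, function(p) {
    tl <- terms[vapply(terms, `[[`, "", "parameter") == p]
    ord <- order(vapply(tl, function(t) t$kind != "intercept", TRUE))
    lapply(tl[ord], make_block, data = data)
  })
  names(out) <- params
  structure(out, class = "anemap_design")
}

make_block <- function(term, data) {
  for (cv in term$covariates)
    if (!cv %in% names(data))
      stop("covariate '", cv, "' not found in data")
  n <- nrow(data)
  blk <- list(term = term, label = paste0(term$parameter, ":", term$name))
  if (term$kind == "intercept") {
    blk$X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
    blk$K <- NULL
  } else if (term$kind == "linear") {
    v <- data[[term$covariates]]
    if (is.numeric(v)) {
      blk$X <- matrix(v, ncol = 1L, dimnames = list(NULL, term$covariates))
    } else {
      v <- as.factor(v)
      blk$levels <- levels(v)
      X <- stats::model.matrix(~v)[, -1L, drop = FALSE]
      colnames(X) <- paste0(term$covariates, levels(v)[-1L])
      blk$X <- X
    }
    blk$K <- NULL
  } else if (term$kind == "pspline") {
    B <- bspline_basis(data[[term$covariates]], term$n_basis, term$degree)
    blk$knots <- attr(B, "knots")
    blk$X <- B
    blk$K <- difference_penalty(term$n_basis, term$penalty_order)
  } else if (term$kind == "spatial_tensor") {
    tb <- tensor_spatial_basis(data[[term$covariates[1L]]],
                               data[[term$covariates[2L]]],
                               n_basis = term$n_basis, degree = term$degree,
                               penalty_order = term$penalty_order)
    blk$knots <- tb$knots
    blk$X <- tb$X
    blk$K <- tb$K
  } else if (term$kind == "random_intercept") {
    f <- as.factor(data[[term$covariates]])
    blk$levels <- levels(f)
    X <- stats::model.matrix(~ f - 1)
    colnames(X) <- paste0(term$covariates, levels(f))
    blk$X <- X
    blk$K <- diag(ncol(X))
  }
  smooth <- term$kind %in% c("pspline", "spatial_tensor")
  blk$Z <- if (smooth) constraint_null(blk$X) else diag(ncol(blk$X))
  # linear columns are centered at their training means so they stay
  # orthogonal to the intercept (decorrelates blockwise updates); the
  # centers are stored and re-applied at prediction time
  if (term$kind == "linear") blk$center <- colMeans(blk$X)
  blk$XZ <- blk$X %*% blk$Z
  if (!is.null(blk$center))
    blk$XZ <- sweep(blk$XZ, 2L, blk$center)
  if (!is.null(blk$K)) {
    blk$KZ <- crossprod(blk$Z, blk$K %*% blk$Z)
    blk$KZ <- (blk$KZ + t(blk$KZ)) / 2
    blk$rank <- psd_rank(blk$KZ)
  }
  blk
}

# Rebuild the raw basis of a block at new data and return the constrained
# design (newX %*% Z).  Out-of-range values are clamped by bspline_basis.
eval_block <- function(blk, newdata) {
  term <- blk$term
  X <- switch(term$kind,
    intercept = matrix(1, nrow(newdata), 1L),
    linear = {
      v <- newdata[[term$covariates]]
      if (!is.null(blk$levels)) {
        v <- factor(v, levels = blk$levels)
        if (anyNA(v)) stop("unknown level in '", term$covariates, "'")
        stats::model.matrix(~v)[, -1L, drop = FALSE]
      } else matrix(v, ncol = 1L)
    },
    pspline = bspline_basis(newdata[[term$covariates]], term$n_basis,
                            term$degree, knots = blk$knots),
    spatial_tensor = tensor_spatial_basis(
      newdata[[term$covariates[1L]]], newdata[[term$covariates[2L]]],
      n_basis = term$n_basis, degree = term$degree,
      penalty_order = term$penalty_order, knots = blk$knots)$X,
    random_intercept = {
      # unseen levels (e.g. held-out clusters) get a zero row: the
      # population-level prediction marginalizes the random effect at 0
      f <- factor(newdata[[term$covariates]], levels = blk$levels)
      M <- matrix(0, nrow(newdata), length(blk$levels))
      idx <- !is.na(f)
      M[cbind(which(idx), as.integer(f[idx]))] <- 1
      M
    })
  X <- X %*% blk$Z
  if (!is.null(blk$center)) X <- sweep(X, 2L, blk$center)
  unname(X)
}
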