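#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream.  `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Equal-tailed interval + mean of a draws matrix (n_draws x n_units),
# returned as a data.frame with one row per unit.
summarize_draws <- function(draws, level = 0.95) {
  stopifnot(is.matrix(draws), level > 0, level < 1)
  alpha <- (1 - level) / 2
  qs <- apply(draws, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  data.frame(mean = colMeans(draws), lower = qs[1L, ], upper = qs[2L, ])
}

# Great-circle distance in km between (lon, lat) points; vectorized over the
# first argument set.
distance_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2)) / 1000
}

# Mode of a vector (first-most-frequent; ties broken by first appearance in
# sorted factor order for determinism).
stat_mode <- function(x) {
  tab <- table(x)
  val <- names(tab)[which.max(tab)]
  if (is.numeric(x)) as.numeric(val) else val
}

# Fix every non-focal covariate at its median (numeric) or mode (other).
typical_profile <- function(data, cols) {
  out <- lapply(cols, function(cl) {
    v <- data[[cl]]
    if (is.numeric(v)) stats::median(v) else stat_mode(v)
  })
  names(out) <- cols
  out
}
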