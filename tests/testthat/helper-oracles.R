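# Independent oracles, deliberately coded without reference to the package
# internals they check.

# Cox-de Boor recursion for B-spline basis function j (1-based) of order
# `ord` on knot vector `knots`, evaluated at scalar x.
cox_de_boor <- function(x, j, ord, knots) {
  if (ord == 1)
    return(as.numeric(knots[j] <= x & x < knots[j + 1]))
  d1 <- knots[j + ord - 1] - knots[j]
  d2 <- knots[j + ord] - knots[j + 1]
  a <- if (d1 > 0) (x - knots[j]) / d1 * cox_de_boor(x, j, ord - 1, knots) else 0
  b <- if (d2 > 0) (knots[j + ord] - x) / d2 *
         cox_de_boor(x, j + 1, ord - 1, knots) else 0
  a + b
}

# Haversine great-circle distance in km (same Earth radius as the
# geosphere default, 6378137 m).
haversine_km <- function(lon1, lat1, lon2, lat2) {
  r <- 6378.137
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(sqrt(a))
}

# Normal log density sum coded from the formula, not via dnorm.
normal_loglik_oracle <- function(y, mu, sigma) {
  sum(-0.5 * log(2 * pi) - log(sigma) - 0.5 * ((y - mu) / sigma)^2)
}
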