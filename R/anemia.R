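#' WHO severity thresholds for childhood anemia
#'
#' Hemoglobin cutoffs (g/L) for children aged 6-59 months, after altitude
#' adjustment: any anemia below `any`, mild in `[mild_lower, any)`, moderate
#' in `[moderate_lower, mild_lower)`, severe below `moderate_lower`.  All
#' intervals are left-closed, i.e. a child at exactly 100 g/L is mild and a
#' child at exactly 110 g/L is not anemic.
#'
#' @param any,mild_lower,moderate_lower Cutoffs in g/L; must satisfy
#'   `0 < moderate_lower < mild_lower < any`.
#' @return A list of class `severity_thresholds`.
#' @examples
#' severity_thresholds()          # WHO defaults 110 / 100 / 70 g/L
#' @export
severity_thresholds <- function(any = 110, mild_lower = 100,
                                moderate_lower = 70) {
  if (!(moderate_lower < mild_lower && mild_lower < any))
    stop("thresholds must satisfy moderate_lower < mild_lower < any")
  if (moderate_lower <= 0) stop("thresholds must be positive")
  structure(list(any = any, mild_lower = mild_lower,
                 moderate_lower = moderate_lower),
            class = "severity_thresholds")
}

#' Altitude adjustment of measured hemoglobin
#'
#' Applies the CDC/DHS polynomial altitude correction so that hemoglobin
#' measured at elevation is comparable with sea-level thresholds.  Writing
#' `f` for elevation in thousands of feet, the subtracted amount (g/L) is
#' `10 * (-0.032 f + 0.022 f^2)`.  The correction is only active above the
#' activation altitude (default 1000 m); below it the value is returned
#' unchanged.  The adjustment depends on elevation only, so it is additive:
#' the same amount is subtracted whatever the measured level.
#'
#' @param hb Measured hemoglobin, g/L (> 0).
#' @param elevation Elevation in meters; finite, vectorized with `hb`.
#' @param activation_m Altitude (m) below which no adjustment is applied.
#' @param adjust_fn Optional replacement adjustment: a function of elevation
#'   (m) returning the amount (g/L) to subtract.  Allows swapping in an
#'   alternative published table.
#' @return Adjusted hemoglobin, g/L.
#' @examples
#' adjust_hb_for_altitude(110, 0)      # unchanged at sea level
#' adjust_hb_for_altitude(120, 2000)   # about 112.6 g/L
#' @export
adjust_hb_for_altitude <- function(hb, elevation, activation_m = 1000,
                                   adjust_fn = NULL) {
  if (any(!is.finite(hb)) || any(!is.finite(elevation)))
    stop("hb and elevation must be finite")
  if (any(hb <= 0)) stop("hb must be positive")
  if (is.null(adjust_fn)) {
    adjust_fn <- function(elev) {
      f <- elev * 0.0032808           # meters -> thousands of feet
      10 * (-0.032 * f + 0.022 * f^2) # g/dL polynomial, scaled to g/L
    }
  }
  adj <- ifelse(elevation > activation_m, adjust_fn(elevation), 0)
  hb - adj
}

#' Classify an (adjusted) hemoglobin level into a severity class
#'
#' @param adjusted_hb Altitude-adjusted hemoglobin, g/L; finite.
#' @param thresholds A [severity_thresholds()] object.
#' @return Factor with levels `none`, `mild`, `moderate`, `severe`; exactly
#'   one class per value (the four intervals partition the real line).
#' @examples
#' classify_severity(c(110, 105, 70, 69.999))
#' @export
classify_severity <- function(adjusted_hb, thresholds = severity_thresholds()) {
  if (any(!is.finite(adjusted_hb))) stop("adjusted_hb must be finite")
  out <- ifelse(adjusted_hb >= thresholds$any, "none",
         ifelse(adjusted_hb >= thresholds$mild_lower, "mild",
         ifelse(adjusted_hb >= thresholds$moderate_lower, "moderate",
                "severe")))
  factor(out, levels = c("none", "mild", "moderate", "severe"))
}

#' Severity-class probabilities under a fitted response distribution
#'
#' Closed-form probabilities of each anemia class given the response
#' distribution of hemoglobin with parameters `mu` and `sigma`: with `F`
#' the response CDF, `p_any = F(110)`, `p_mild = F(110) - F(100)`,
#' `p_moderate = F(100) - F(70)` and `p_severe = F(70)` (WHO defaults).
#' By construction `p_mild + p_moderate + p_severe = p_any`.
#'
#' @param mu,sigma Distribution parameters (g/L); `sigma > 0`.  Vectorized.
#' @param thresholds A [severity_thresholds()] object.
#' @param family An `anemap_family`; defaults to the Normal family.
#' @return A data.frame with columns `p_any`, `p_mild`, `p_moderate`,
#'   `p_severe`, one row per (mu, sigma) pair.
#' @examples
#' severity_probabilities(100, 10)   # p_any = pnorm(1) = 0.841...
#' @export
severity_probabilities <- function(mu, sigma,
                                   thresholds = severity_thresholds(),
                                   family = gaussian_ls()) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  f_any <- family$cdf(thresholds$any, mu, sigma)
  f_mild <- family$cdf(thresholds$mild_lower, mu, sigma)
  f_mod <- family$cdf(thresholds$moderate_lower, mu, sigma)
  data.frame(p_any = f_any,
             p_mild = f_any - f_mild,
             p_moderate = f_mild - f_mod,
             p_severe = f_mod)
}
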