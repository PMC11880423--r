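---
title: "Distributional regression mapping of childhood anemia: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributional regression mapping of childhood anemia: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anemap)
```

## The problem

Childhood anemia is diagnosed from the hemoglobin (Hb) concentration in
blood: after altitude adjustment, a child aged 6–59 months is anemic below
110 g/L, with mild `[100, 110)`, moderate `[70, 100)` and severe `< 70` g/L
classes.  Because every severity class is a tail (or interval) probability
of the *same* continuous response, a model of the full conditional
distribution of Hb delivers all severity prevalences at once, coherently:
estimate `P(Hb < t | x, s)` for each threshold `t` at covariates `x` and
location `s`, and the class probabilities follow by differencing.

`anemap` implements this program end to end for geo-referenced,
cluster-sampled household surveys (DHS-like): a synthetic survey generator
with known ground truth, structured additive location-scale regression
estimated by gradient-boosting term selection followed by MCMC, severity
classification, pixel-level prevalence mapping with credible intervals,
population-weighted administrative aggregation, and predictive calibration
diagnostics.

## The model

The response is modeled with a Normal location-scale (distributional,
GAMLSS-type) regression:

$$ y_i \sim \mathcal{N}\!\left(\mu(x_i, s_i),\ \sigma(x_i, s_i)^2\right), $$

where both parameters carry their own structured additive predictor,

$$ \mu = \eta_\mu = \textstyle\sum_j f_j(x),\qquad
   \log \sigma = \eta_\sigma = \textstyle\sum_k g_k(x). $$

The identity link for the mean and log link for the scale guarantee a
valid parameter pair for any predictor value.  Each additive term is one
of:

* **linear** terms (numeric or dummy-coded categorical), columns centered
  at training means so they stay orthogonal to the intercept;
* **P-splines**: cubic B-spline bases (20 functions by default) with
  equally spaced knots over the observed range and a second-order
  difference penalty;
* **spatial tensor products**: row-wise Kronecker products of marginal
  B-spline bases in longitude and latitude (10 functions per margin), with
  the additive penalty `K_lon ⊗ I + I ⊗ K_lat`;
* **random intercepts** for survey clusters (identity penalty).

Smooth terms carry a sum-to-zero constraint (QR reparameterization) so
they are identified next to the intercept.  Basis family, knot counts and
penalty orders are explicit package defaults in standard P-spline
practice; all are configurable per term.

### Anemia severity

With `F` the fitted response CDF, `p_any = F(110)`,
`p_mild = F(110) − F(100)`, `p_moderate = F(100) − F(70)` and
`p_severe = F(70)`; the intervals are left-closed and telescope exactly:
`p_mild + p_moderate + p_severe = p_any`.  The altitude adjustment
implements the CDC/DHS polynomial (in thousands of feet `f`, subtract
`10(−0.032 f + 0.022 f²)` g/L), active above 1,000 m; the adjustment
function is swappable and the synthetic pipeline can run with adjustment
disabled, because published practice varies and survey files may already
contain adjusted values — both paths are supported.

## Term selection by noncyclic boosting

Candidate terms for both parameters compete jointly: at each iteration,
every candidate block is fitted by penalized least squares to its
parameter's *working gradient* (score divided by expected information — a
Fisher-scoring step, which keeps update magnitudes on the predictor scale
and comparable between the mean and the scale), and the single block whose
damped update (learning rate 0.1) most improves the training
log-likelihood is updated.  Penalized base learners are weakened to a
fixed effective-degrees-of-freedom target (4) so blocks of different size
compete fairly.  Selection frequencies — the share of iterations each term
won — are the importance measure; terms at or above a frequency floor
(default 0.05) are passed to the MCMC stage, and intercepts are always
retained.  The iteration budget (default 200) is fixed configuration, not
tuned internally: the goal of this stage is a reduced term set, not final
estimates.  Ties in improvement are broken by fixed term order, making the
stage fully deterministic.

## Bayesian estimation

The selected model is estimated by blockwise MCMC:

* Unpenalized coefficient blocks have flat priors; each penalized block
  has the partially improper Gaussian smoothing prior
  `b ~ N(0, τ² K⁻)`, with `τ² ~ InverseGamma(0.001, 0.001)` drawn from its
  conjugate full conditional given the penalty quadratic form.
* Each block's coefficients are proposed from an IWLS Gaussian
  approximation to the full conditional (precision `XᵀWX + K/τ²` with
  expected-information weights).  For the Normal mean this approximation
  is exact, so those blocks are Gibbs updates with acceptance 1.
* Non-conjugate blocks (the scale, and all blocks of non-Normal families)
  use Metropolis–Hastings with a 50/50 mixture kernel: the IWLS
  independence-style proposal (fast mixing near stationarity) and a
  preconditioned random-walk proposal scaled by `2.4/√p`.  The mixture is
  important: a pure mode-seeking IWLS proposal can strand the chain when
  the current state is far from the conditional mode, because the reverse
  proposal density vanishes; the random-walk component restores
  irreducibility in that regime.  The walk is symmetric for the shipped
  families because a block's expected weights do not depend on its own
  coefficients.
* Near-singular proposal precisions are repaired by automatic ridge
  escalation (starting at `1e-10` of the diagonal scale, escalating
  ×100 up to six times before failing).

Defaults are 12,000 iterations, 2,000 burn-in, thinning 10 (1,000 stored
draws); acceptance rates are recorded per block and a Geweke-style
first-vs-last segment diagnostic with batch-means standard errors is
provided.  Chains are exactly reproducible under a seed.  Regions
(mainland sub-Saharan Africa, South Asia, Madagascar) are modeled
separately — region is a top-level configuration key, one model per
region — because spatial correlation should not be smoothed across water.

Survey year is an ordinary covariate: with multi-year data it can enter
as a linear term or a P-spline on either parameter.  The synthetic
generator defaults to a single survey year, so the reference scenario
omits a time term rather than fit a degenerate smooth.

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults define the reference study conditions used by the
acceptance experiments: 250 clusters (PSUs) of 20 children over a ~1100 ×
1100 km region; mean Hb = 108 g/L intercept + a piecewise-parabolic age
effect with minimum at 18 months (≈8 g/L dip from 6 to 18 months, ≈15 g/L
rise to 59 months, matching the qualitative profile that anemia risk
peaks in the second year of life) + 3 g/L per SD of household wealth + a
smooth spatial field (variance 25 (g/L)², range 200 km) + an i.i.d.
cluster random intercept (SD 2 g/L); log scale = log(10) + 1.5·10⁻⁴ per m
of elevation about the regional mean.  Elevation, temperature, land cover
and child population are deterministic smooth surfaces shared between the
survey and the pixel grid.  The spatial field is a low-rank Gaussian bump
basis rescaled to an exact pointwise variance — smoothness, not covariance
exactness, is what downstream stages need.

The generator does **not** emulate DHS sampling weights, stratification,
non-response, measurement digit preference, or real geography; the
within-PSU dependence of real surveys is unknown, so the i.i.d. Normal
cluster intercept is an explicit stand-in (configurable, `cluster_sd = 0`
switches it off).  Passing calibration tests on these data therefore
demonstrates the correctness of the machinery under the stated model, not
the adequacy of the Normal family or the covariate set for any real
survey.

## Mapping and aggregation conventions

* Pixel grids default to 20 × 20 km.  Pixels that are barren or permanent
  snow/ice, or above 3,750 m (1,900 m for Madagascar), are masked and emit
  no estimate.
* Map products fix non-geo-referenced covariates at the training median
  (numeric) or mode (categorical) and marginalize random intercepts at
  zero; age-stratified maps average severity probabilities over the
  integer months of the bin with equal weight (the within-bin age
  distribution is not modeled).  The stratified bins are (6, 24],
  (24, 42] and (42, 60] months, with the last capped at 59 — the data stop
  there, although the printed bin label reads 60.
* Marginal-effect curves at a location fix all other covariates at the
  median/mode observed among survey records within a 20 km great-circle
  (haversine) buffer; an empty buffer is an error naming the location and
  radius.  Spline prediction outside the training covariate range clamps
  to the boundary with a warning — polynomial tails are never
  extrapolated into unsurveyed pixels.
* Administrative aggregation is the population-weighted mean of pixel
  prevalences computed *per posterior draw*, then summarized: intervals
  propagate the joint posterior rather than averaging pixel intervals.
  Affected-children counts multiply per-draw prevalence by the population
  at risk.  Trend classification between two years uses percentage-point
  differences with the symmetric ±2 band (the printed worked examples are
  consistent with point differences, not relative changes).

## Calibration diagnostics

Validation splits 80/20, by cluster by default so no PSU contributes to
both sides (record-level splitting is available to match the literal
80/20-of-records convention).  For each held-out record the probability
integral transform `u = F̄(y)` uses the posterior predictive mixture CDF
(averaging the response CDF over parameter draws); a calibrated model
yields uniform `u` (10-bin histogram, Kolmogorov–Smirnov distance, and a
chi-square uniformity test that detects the U-shape of underdispersed
predictives).  The 95% posterior prediction interval (PPI) is the
equal-tailed interval of the same mixture, inverted by bisection;
out-of-sample coverage should be approximately 95%.  Admin-2 validation
correlates model-aggregated prevalence with design-naive direct survey
estimates (pooled classified records per unit); DHS design weights are
out of scope, so the direct estimates are unweighted.

## Numerical choices and degenerate inputs

* B-splines are evaluated just inside the right boundary knot so the
  closed-interval limit is returned (partition of unity holds at the
  maximum); degenerate constant covariates get a ±0.5 pseudo-range.
* Zero-variance spatial fields return exact zeros; admin units with zero
  population are skipped with a warning; empty candidate sets, empty
  buffers, empty partitions and unknown covariates or region labels are
  errors naming the offending input.
* Penalty ranks are computed from eigenvalues with a relative `1e-8`
  tolerance; constrained penalties are symmetrized before factorization.
* Boosting stops early if no candidate improves the likelihood, keeping
  the log-likelihood path non-decreasing; frequencies are shares of
  iterations actually run.

## Problem sizes used by the shipped experiments

The reference calibration study (`run_calibration_study()`) uses 5,000
children in 250 clusters, 200 boosting iterations and a single
12,000-iteration chain — a desk-scale configuration chosen so the full
pipeline, including the pixel map and admin validation, completes in a
few minutes.  Replicate experiments (coefficient recovery, boosting
support recovery, PIT sensitivity) run 20–100 replicates at n = 2,000 to
4,000 with shorter chains; these sizes are stated in the test files next
to the assertions they support.

## Known limitations

* Single-chain inference; seed-independent multi-chain convergence
  assessment is left to the user (the draws are plain matrices).
* No Markov random fields, thin-plate splines, or space × time
  interaction tensors; the spatial tensor plus an additive year term is
  the most complex predictor shipped.
* The Normal family is the default and only fully supported response; the
  family contract is pluggable (a fixed-shape Student-t ships for contract
  tests) but skewed or four-parameter families are not provided.
* Prediction at covariate values outside the training range is clamped,
  which biases extreme-pixel estimates toward the boundary fit rather
  than extrapolating — a deliberate conservatism.
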