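---
title: "Latent state-trait models with autoregressive effects: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent state-trait models with autoregressive effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lstar)
```

## The model

`lstar` implements two confirmatory factor models for longitudinal panel
data on an approximately interval scale: a latent state-trait model with
autoregressive effects (LST-AR) for one rater, and its multi-rater
extension (MR-LST-AR) for dyads in which two raters report on their mutual
relationship.

In the single-rater model, each observed indicator $Y_{il}$ (indicator $i$,
occasion $l$) decomposes into an intercept, an error-free latent state and
measurement error.  The state itself splits into an indicator-specific
trait factor $T_{i1}$, fixed at the first occasion, and an occasion factor
$O_l$ shared by all indicators of the occasion:

$$Y_{il} = a_{il} + \lambda_{T,il}\, T_{i1} + \lambda_{O,il}\, O_l + E_{il},$$

with $\lambda_{T,i1} = 1$ and $\lambda_{O,1l} = 1$ for identification.  The
occasion factors follow a first-order autoregression,

$$O_1 = SR_1, \qquad O_l = \beta_{O,l}\, O_{l-1} + SR_l \;(l > 1),$$

so the state residuals $SR_l$ are occasion-specific shocks and $\beta_{O,l}$
carries them forward.  All factors are zero-mean; the observed means are
carried entirely by the intercepts.  This structure lets the package
separate three sources of interindividual differences at each occasion:
first-occasion trait differences, accumulated situational carry-over, and
current occasion-specific effects — the quantities behind the
predictability/unpredictability and occasion-specificity coefficients, and
behind the contrast between a prototype-like account of stability (trait
predictability plateaus above zero) and a revisionist account (it decays
toward zero).

The two-rater extension is a CT-C(M−1) multitrait-multimethod structure:
one rater (by default rater 1) is the reference, and the other rater's
indicators load both on the reference rater's factors and on rater-specific
residual factors $TPS_{i}$ (trait level) and $OPS_l$ (occasion level, with
its own autoregression driven by $SRPS_l$):

$$Y_{i2l} = a_{i2l} + \lambda_{T,i2l} T_{i1} + \lambda_{TPS,i2l} TPS_{i}
          + \lambda_{O,i2l} O_l + \lambda_{OPS,i2l} OPS_l + E_{i2l}.$$

Because the rater-specific factors are residuals, they are uncorrelated
with the same-indicator reference factors by definition; this is a fixed
zero, never a free parameter.  Shared versus rater-specific variance yields
the rater-consistency system (`RS`, `RCon`, `RConPred`, `RConTCon`,
`RConOS` and their complements), and the square roots of the consistency
coefficients are error-free correlations between the raters' ratings.

## Invariance constraints and degrees of freedom

The default constraint set encodes measurement invariance over time: equal
occasion-factor loadings, equal state-residual variances (including the
first occasion) and equal autoregressive weights, each per rater-side
process.  Two layout decisions deserve a note, because the degrees of
freedom are a deterministic function of them:

* `Var(SR_l)` is tied across *all* occasions including occasion 1, and one
  autoregressive weight is shared by all transitions.  With 3 indicators
  and 4 occasions this gives 43 free parameters against 90 observed
  moments, hence `df = 47` for the single-rater model.
* In the two-rater model the cross-indicator covariances
  `Cov(TPS_i, T_j)`, `i != j`, are free by default (the residual definition
  only forces the same-indicator covariance to zero).  This yields 107 free
  parameters against 324 moments, hence `df = 217`.  The flag
  `mr_tps_cross_trait_covariances` removes these six covariances for users
  who prefer the stricter layout; the df arithmetic alone cannot decide
  between the two, so both are first-class options.
* The occasion-1 loadings of the state residual (`lambda_SR`) are stored as
  the occasion-1 column of the occasion-factor loadings and tied to the
  later occasions under invariance, since `O_1 = SR_1` makes occasion 1
  structurally identical to the later occasions.

```{r df}
model_df(lst_spec(3, 4, 1))
model_df(lst_spec(3, 4, 2))
```

## Estimation

Fitting is full-information maximum likelihood: each dyad contributes the
multivariate-normal log-density of its observed subvector under the
corresponding sub-moments, so missing entries need no imputation and the
estimates are consistent under ignorable (MAR) missingness.  Rows are
grouped by missingness pattern and reduced to sufficient statistics, which
makes one likelihood evaluation independent of the number of dyads.

Numerical choices, all package defaults a user can override:

* **Parameterization.**  Variances (state-residual, rater-specific
  state-residual, error, trait-block diagonals) are optimized on the log
  scale; covariances, loadings, intercepts and autoregressive weights on
  the natural scale.  The trait covariance block is therefore symmetric by
  construction but *not* forced positive definite: a Heywood-type boundary
  solution remains visible and is flagged on the fit object rather than
  silently truncated.
* **Optimizer.**  Quasi-Newton (`nlminb`) on the flat unconstrained vector
  with an analytic gradient (the pattern-wise derivative with respect to
  the mean and covariance propagated through the loading structure and the
  AR recursion; the compiled core also provides a central-difference
  gradient, used only to cross-check the analytic one in the test suite).
  Iteration cap 2000; relative objective tolerance 1e-10; a fit is declared
  converged when the optimizer reports success or the gradient max-norm
  falls below 1e-3 on the log-likelihood scale.  If the first start fails,
  up to three jittered restarts with fixed sub-seeds are tried.
* **Starting values.**  Deterministic and data-driven: intercepts at column
  means, error variances at half the column variances, trait blocks from
  occasion-averaged indicator covariances, free loadings 1 (0.5 for the
  non-reference rater's loadings on shared factors), autoregressive weights
  0.3.
* **Fit indices.**  The saturated model is estimated by EM for the
  multivariate normal under missingness (closed form with complete data);
  the baseline model is the independence model, whose ML solution
  factorizes per column even with missing data.  `chi2 = 2(ll_sat -
  ll_mod)`, CFI from the baseline chi-square, and RMSEA with the `(n - 1)`
  convention, where `n` counts rows retained after dropping all-missing
  rows.  The plain ML chi-square is reported — no robust (sandwich-type)
  correction is applied, so values will differ slightly from software that
  rescales the test statistic.
* **Standard errors.**  Inverse of the numerically differentiated observed
  information at the maximizer, mapped to the natural scale through the
  parameterization's Jacobian.
* **Bootstrap.**  Nonparametric over dyads (whole rows, preserving
  within-dyad dependence), percentile intervals, replicates started at the
  full-sample estimate; non-converged replicates are dropped and counted,
  with a warning above 20%.
* **Degenerate inputs.**  A non-positive-definite observed sub-block yields
  a large finite penalty instead of `NaN`; zero true variance makes the
  affected coefficient an explicit `NA`, never a silent zero.

## Coefficients

All variance-decomposition coefficients are ratios of structural variance
components and are therefore invariant to a common rescaling of the
observed variables.  Exact identities — occasion specificity plus time
consistency equal one, predictability plus unpredictability equal time
consistency, rater specificity plus rater consistency equal one — hold
algebraically for every valid parameter set and are enforced by tests, not
by construction tricks in the code.

Two conventions required a decision:

* **Occasion 1.**  Time consistency and trait predictability are undefined
  at the first occasion (there is no earlier occasion).  The usual table
  presentation nevertheless prints the trait share of true variance
  (`1 - OS`) in both columns there.  `coefficient_table()` follows that
  convention by default (`occasion1_convention = TRUE`); the low-level
  accessors return `NA` at occasion 1, and the strict behaviour is
  available in the table too.
* **Rater-consistent time consistency.**  The package defines it as the
  shared (reference-rater) time-consistent variance over the total
  time-consistent variance of the non-reference indicator:
  numerator $\lambda_T^2 Var(T) + \lambda_O^2 \beta_O^2 Var(O_{l-1})$,
  denominator the same plus $\lambda_{TPS}^2 Var(TPS) + \lambda_{OPS}^2
  \beta_{OPS}^2 Var(OPS_{l-1})$.  This reconstruction has the two
  properties any candidate must satisfy: it collapses onto the
  rater-consistent trait predictability when both autoregressions vanish,
  and its square root is the correlation between the raters'
  time-consistent components.  It is implemented in exactly this form and
  must not be silently altered.

## The synthetic-data generator

`simulate_lst()` draws first-occasion traits (and rater-specific traits)
from the trait covariance block, generates the occasion processes by the
AR recursions, and adds normal errors.  Its defaults emulate a four-wave
dyadic panel of 575 dyads with the wave participation counts
558/463/428/429 (reference rater) and 405/384/341/323 (second rater):

* Missingness is applied at the rater-wave level — a participant who skips
  a wave misses all indicators of that wave — because that is how panel
  attrition manifests; cell-level MCAR thinning is available as an option.
* Because the reference-rater counts are not monotone (wave 4 exceeds wave
  3), the default mechanism is wave-level MCAR at the observed rates with
  rater-waves independent, not monotone dropout.  A monotone mechanism
  (shared uniform per dyad-rater, so nobody returns after dropping out) is
  provided and validates that its rates are non-increasing.  Real attrition
  is somewhere between the two; the package makes the simplification
  explicit rather than hiding it.
* One master seed drives three separate sub-streams (latents, errors,
  mask), so adding missingness does not perturb the drawn responses.

`example_parameters()` is a deterministic fixture whose coefficient profile
matches what dyadic attachment panels typically show — reliabilities around
0.7, high trait predictability with a small accumulating situational
component for the reference rater, a practically absent one for the second
rater, and rater specificity around 0.85.  It is the truth for the
parameter-recovery and calibration studies.

What passing simulation-based tests does and does not show: the generator
is multivariate normal with wave-level ignorable missingness, exactly the
regime the ML estimator assumes.  Recovery and coverage results under this
generator validate the implementation, not the robustness of the model to
ordinal five-point scales, heavy tails, or nonignorable dropout — real
data depart from the generator in all three ways.

## Problem sizes used in the checks

The package's own validation suite uses: parameter recovery at
n = 5000 (complete) and n = 575 (study missingness profile); a chi-square
calibration of 200 single-rater datasets at n = 500, whose mean is required
to fall within 10% of df = 47; a bootstrap coverage study of 100
replications with B = 500 resamples each on a reduced three-indicator,
three-occasion design at n = 250 (the reduced design keeps 50,000 refits
affordable while exercising the identical code path; with only two
occasions the autoregressive weight is too weakly identified for reliable
refits); and a
one-million-draw Monte-Carlo comparison of the simulated covariance with
the implied moments.

## Known limitations

* Indicators are treated as continuous multivariate normal; ordinal
  five-point responses are approximated, not modeled.
* No robust (MLR-type) chi-square rescaling or sandwich standard errors;
  reported fit indices are plain ML.
* At most two raters, the same indicators for both, and no
  multiple-group estimation with cross-group constraints (subgroup
  analyses are independent runs).
* Occasions are exchangeable labels: equal spacing is metadata, and the
  autoregression is per transition, not per unit time.
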