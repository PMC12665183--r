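---
title: "Stratified instrumental-variable analysis of nonlinear effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified instrumental-variable analysis of nonlinear effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sssiv)
```

## The problem

With a continuous exposure $X$, a continuous outcome $Y$ and unmeasured
confounding $U$, the causal estimand is a whole function: the effect shape
$h(x)$ in the structural model $Y = h(X) + U$, anchored at $h(0) = 0$, or its
derivative $h'(x)$, the effect intensity. A valid instrument $Z$ (associated
with $X$, independent of $U$, no direct path to $Y$) identifies a *scalar*
effect easily, but a nonlinear shape is much more demanding: classical
nonlinear IV regression and control-function methods need either many
distinct instrument values or strong parametric assumptions on the
confounding, and both struggle when the instrument is weak. That is exactly
the situation of Mendelian randomization, where a genetic score typically
explains under 1% of the exposure variance and is often effectively binary.

`sssiv` implements a stratification-based alternative with three stages.

## Stage 1: collider-robust stratification

Stratifying directly on $X$ breaks the instrument: $X$ is a common effect
(collider) of $Z$ and $U$, so selecting on it induces a spurious $Z$–$U$
association within strata. Both methods in the package instead stratify on
(a surrogate for) the *counterfactual exposure* $X(z)$, which is not a
collider:

* `residual_stratify()` assumes a structural exposure model
  $X = t(f(Z) + g_X(U, \epsilon_X))$ with known monotone transform $t$
  (identity or log), estimates $f$ by least squares, and groups individuals
  into $K$ equal-size quantile bins of the predicted counterfactual exposure
  at the reference level $z_0 = 0$. Remainder rows go to the lowest strata.
* `doubly_ranked_stratify()` assumes only *rank preservation* — an
  individual keeps the same exposure rank whatever instrument value it is
  assigned. Rows are sorted by $Z$, cut into $\lfloor n/K\rfloor$ pre-strata
  of $K$ consecutive rows, and stratum $k$ collects the $k$-th smallest
  exposure from every pre-stratum. Trailing rows that do not fill a
  pre-stratum are dropped and counted. Ties in either ranking are broken by
  row order, so the assignment is deterministic without any RNG.

Rank preservation is weaker than the structural exposure model (every model
of that form satisfies it), which is why the doubly-ranked method is the
default in the pipeline. The test suite verifies the collider-bias contrast
directly: on simulated data with $Z \perp U$, within-stratum $Z$–$U$
correlations are centred on zero for both methods but systematically nonzero
for naive exposure stratification.

## Stage 2: stratum summaries and the weight function

Within stratum $k$, the Wald ratio
$\hat\beta_k = \widehat{\mathrm{Cov}}(Z, Y \mid k) / \widehat{\mathrm{Cov}}(Z, X \mid k)$
converges to $\int h'(x) W_k(x)\,dx$, where
$W_k(x) = \mathrm{Cov}(Z, I\{X \ge x\} \mid k) / \mathrm{Cov}(Z, X \mid k)$
is the stratum weight function: it integrates to exactly one, and under
joint normality of $(Z, X)$ equals the exposure density. Each stratum is a
small, internally valid IV analysis whose estimate is a known local
averaging of the global intensity — that is what makes the aggregation
stages possible.

`stratum_summaries()` computes, per stratum: the associations, the Wald
ratio, its standard error (first-order $\mathrm{se}(\hat\theta)/|\hat\alpha|$
by default, matching common inverse-variance-weighting practice; a
second-order version adds the $\hat\alpha$ uncertainty), the exposure mean,
and $\widehat W_k$ stored as an *exact step function* (breakpoints at the
stratum's distinct exposure values). Storing breakpoints and heights rather
than grid samples means every inner product used later — polynomial moments,
indicator tail masses, B-spline integrals — is computed by exact piecewise
integration, and $\int \widehat W_k = 1$ holds to machine precision by a
telescoping identity. A parametric alternative
(`parametric_weight_function()`) uses only the stratum mean and standard
deviation via the normal form. Strata whose instrument–exposure association
has $|t| < 2$ are flagged weak and retained by default (`drop_weak = TRUE`
excludes them); the exact cut-off is a convention, not an estimate.

`linearity_q_test()` is Cochran's $Q$ against the inverse-variance-weighted
pooled estimate on $K - 1$ degrees of freedom: under a constant intensity
all strata share one estimand, so heterogeneity is evidence of nonlinearity
(or effect modification, which stratification cannot distinguish).

## Stage 3a: scalar-on-function and scalar-on-scalar regression

Expanding $h'(x) = \sum_l b_l \phi_l(x)$ turns the stratum relation into an
ordinary heteroscedastic regression with design entries
$\langle \phi_l, W_k \rangle$ (scalar-on-function, `fit_sof()`) or the
approximation $\phi_l(\bar x_k)$ (scalar-on-scalar, `fit_sos()`), solved in
closed form with an optional roughness penalty
$\lambda \int (D^m h')^2$:
$\hat b = (X^\top \Sigma^{-1} X + \lambda R)^{-1} X^\top \Sigma^{-1}\hat\beta$,
with the sandwich covariance for inference. Defaults: penalty derivative
order $m = 2$ and a log-spaced $\lambda$ grid $10^{-4}\ldots10^4$ (17
points) for `select_lambda_gcv()`, which minimizes the generalized
cross-validation criterion on the whitened system; when the basis is fixed
a priori (polynomial or oracle bases) no penalty is needed and $\lambda = 0$
is used. The indicator (change-point) family has no square-integrable
derivative, so its penalty matrix is zero and it is fitted unpenalized.
`effect_curve()` reconstructs $\hat h'$ and
$\hat h(x) = [\int_0^x \phi]^\top \hat b$ with exact antiderivatives —
$h(0) = 0$ holds identically, for every basis — and pointwise Wald bands
(no simultaneous adjustment).

Two numerical conventions deserve note. First, indicator bases use the
open-set convention $I\{x > t\}$ at evaluation time: the hinge
$(x - t)_+$ is continuous, its one-sided derivatives at $t$ disagree, and
the open convention keeps the fitted intensity consistent with a jump
intensity $I\{x > 0\}$ evaluated *at* the threshold; inner products are
unaffected. Second, B-spline inner products against step weights use
Gauss–Legendre quadrature with enough nodes to be exact for the spline
degree on every (step × knot-span) piece, so the "exact integration"
contract extends to splines.

### What the weight function does and does not identify

A practical caveat that the simulations below make visible: with a very
weak instrument, the stratum weight functions do not concentrate on the
stratum's own exposure range the way its empirical distribution does, and
the estimated step weights are themselves noisy ratios of small
covariances. The consequence is that the identified intensity *slope* away
from the exposure centre is attenuated for both SoS and SoF fits — the
centre value $h'(\mathbb{E}X)$ is recovered well, outer quantiles less so.
This is a property of the estimand under weak instruments, not an
implementation artifact: the benchmark MSE cells reproduce it, and both
regression routes agree with each other closely.

## Stage 3b: change-point model and the sum-of-single-effects fit

Writing $h'(x) = b_0 + \sum_p b_p I\{x \ge t_p\}$ over a dense candidate
grid $t_1 < \cdots < t_P$ (typically $P \gg K$) turns shape estimation into
sparse regression: `build_changepoint_design()` fills the $K \times (P+1)$
design with exact tail masses $\int_{t_p}^\infty W_k$, the intercept slot
being the potential global linear effect. Default candidate grids
(`changepoint_candidates()`): the middle 90% percentile grid of the
exposure for roughly symmetric exposures, the left 95% grid (including the
lowest percentile) for right-skewed ones — dense enough that the true
change-point is bracketed, which is all the method needs.

`susie_changepoint()` fits the sparse model with a from-scratch
Sum-of-Single-Effects sampler-free procedure: the coefficient vector is a
sum of $L$ (default 10) single effects, each placing all its mass on one
candidate slot with a normal effect-size prior
$N(0, \sigma_0^2)$ and uniform inclusion prior. Because the residual
variances are *known* from the stratum standard errors, the system is
whitened by $\Sigma^{-1/2}$ once and no residual variance is estimated.
Iterative Bayesian stepwise selection cycles through the effects,
residualizing each against the others and applying the exact
single-candidate posterior (`single_effect_posterior()`, computed in log
space and verified in the tests against brute-force marginal-likelihood
enumeration to $10^{-10}$). Each effect's $\sigma_0^2$ is re-profiled every
pass by 1-D maximization of its marginal likelihood with an explicit
comparison against the null; effects whose profiled variance stays below
$10^{-8}\,\mathrm{Var}$(whitened response) are inert, and the count of
non-inert effects is the effective number of detected change-points
$L^\*$. Convergence: maximum absolute change of the posterior-mean
coefficient vector below $10^{-6}$, at most 100 passes (a warning, not an
error, on non-convergence).

Outputs: per-effect posterior inclusion probabilities (each row sums to 1,
with the intercept slot participating as an ordinary candidate), credible
sets in both conventions — smallest descending-PIP set (`credible_set()`)
and central two-sided interval over the ordered candidates
(`changepoint_summary()`, which also reports posterior mode and mean of the
threshold) — counterfactual predictions via the hinge contrasts
$f(x^*; X_i, t_p) = (x^* - t_p)_+ - (X_i - t_p)_+$ (the intercept slot
behaves as $t_0 = -\infty$, a pure linear term), and
`posterior_effect_curve()`, whose point estimate is exactly zero at $x = 0$
and whose pointwise credible band is formed from (default) 10,000 joint
posterior draws — candidate slots and effect sizes drawn per effect, so
each sampled curve is coherent across the grid.

## The simulation module

`generate_iv_data()` reproduces the study designs used throughout
validation, with the instrument effect fixed at 0.15 (additive) or 0.3
(log-scale), i.e. an instrument $R^2$ of about 0.003 (binary $Z$) or 0.01
(normal $Z$) — deliberately weak, as in genetic applications:

* **Part I** (linear truth, $n = 5000$): binary or normal instrument
  crossed with simple additive or deliberately misspecified complex
  confounding ($|U| + \epsilon_X^2 + 2|U||\epsilon_X|$), for comparing
  estimators that do or do not model the confounding.
* **Part II** ($n = 50{,}000$): smooth quadratic intensity $1 + 2x$ versus
  jump intensity $I\{x > 0\}$ (the hinge effect $(x)_+$), the SoS/SoF
  stress test.
* **Part III** ($n = 50{,}000$): normal and lognormal exposures crossed
  with linear, one-change-point, two-change-point and smooth quadratic
  intensity cases, all anchored at $h(0) = 0$.

Oracle comparators `fit_control_function()` (two-step residual inclusion
with the true quadratic form) and `fit_iv_regression()` (exact-identified
2×2 moment system on the dichotomized instrument; empirical-median split
for continuous instruments, which avoids assuming the instrument's
distribution) provide the reference points. Singular fits are reported as
failures and excluded from benchmark cells with a count, since how such
rare failures were originally handled is not documented.

What the generator does *not* emulate: covariates and effect modification,
invalid instruments (pleiotropy), coarsened or measured-with-error
exposures, non-Gaussian confounding beyond the Part I cases. Passing
benchmarks therefore demonstrate correctness of the machinery under the
stated structural models, not robustness to those violations.

`run_benchmark()` loops seeded replicates (one deterministic seed per
replicate drawn from the master seed; the loop is serial, so results are
independent of any parallel execution plan), evaluates estimated shapes
(Parts I/III) or intensities (Part II) at *theoretical* exposure quantiles
computed from the closed-form exposure law (normal, two-component normal
mixture, or their exponentials; mixture quantiles by root-finding), and
averages squared errors with a Monte-Carlo standard error per cell. The
shipped acceptance script uses 200 replicates per configuration —
Monte-Carlo standard errors there are a few percent of each cell, which is
the resolution the reproduction claims are made at.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
ds <- generate_iv_data(scenario_spec("III", scenario = 1, effect_case = 2,
                                     n = 50000, seed = 7))
res <- run_pipeline(ds$data, method = "doubly_ranked", K = 100,
                    model = "changepoint", L = 10, seed = 7)
res$q_test$p_value        # linearity rejected
changepoint_summary(res$fit)   # one detected effect, mode near the true 0
head(res$curve)           # posterior effect curve with credible band
```

## Design choices made where the design was open

* The reference instrument level for residual stratification is fixed at
  $z_0 = 0$: only the ordering of the predicted counterfactual exposure
  matters for quantile grouping, so the choice is inconsequential.
* Remainders: the doubly-ranked method drops trailing rows after the
  $Z$-sort; the residual method pads the lowest strata. Both are logged.
* Pre-strata contain exactly $K$ individuals (one per stratum per
  pre-stratum); coarser pre-strata are not offered.
* Weak-stratum handling is warn-and-retain by default because dropping
  changes the estimand; the $|t| < 2$ rule is a convention.
* The linearity test is plain Cochran's $Q$, and is labelled as such.
* Fit failures in benchmark cells are excluded with a reported count.
* Credible sets are emitted in both the descending-PIP and central-interval
  conventions, since both are in circulation.
* For the lognormal designs the theoretical evaluation quantiles are the
  closed-form quantiles of $\exp N(0,\, 2 + 0.09\,\mathrm{Var}(Z))$ (or the
  corresponding two-component mixture for a binary instrument).

## Known limitations

Single-instrument analyses only (a multi-variant genetic score is assumed
to be collapsed upstream); no invalid-instrument extensions; pointwise
rather than simultaneous bands; the change-point model deliberately
restricts $h'$ to piecewise-constant forms — a smooth intensity yields many
small detected effects and wide bands, which the pipeline flags with an
advisory to switch to a parametric basis.
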