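# sssiv

Stratification-based instrumental-variable (IV) analysis of **nonlinear
causal effects** — the setting of nonlinear Mendelian randomization, where a
single weak (often binary or few-valued) instrument such as a genetic score
must identify a whole effect *function*, not one number.

Given individual-level data `(Z, X, Y)` — instrument, continuous exposure,
continuous outcome — under the structural model `Y = h(X) + U` with
unmeasured confounding `U` and `h(0) = 0`, the package estimates the effect
shape `h(x)`, its intensity `h'(x)`, and the location of change-points in
`h'`, through three stages:

1. **Stratification.** The sample is split into `K` strata on (a surrogate
   for) the *counterfactual* exposure, so that `Z ⫫ U` survives within each
   stratum — stratifying on the observed exposure would condition on a
   collider and break the instrument. Two methods: residual stratification
   (`residual_stratify()`, structural exposure model) and doubly-ranked
   stratification (`doubly_ranked_stratify()`, rank-preserving assumption:
   sort by `Z` into pre-strata of `K`, rank `X` within pre-strata, match
   ranks across pre-strata).

2. **Stratum summaries → functional regression.** Each stratum yields a
   Wald ratio `β̂_k = Cov(Z,Y|k)/Cov(Z,X|k)` with standard error, and an
   exact step-function estimate of the weight function
   `W_k(x) = Cov(Z, 1{X ≥ x}|k)/Cov(Z,X|k)`, which satisfies
   `β̂_k → ∫ h'(x) W_k(x) dx` and `∫ W_k = 1` (to machine precision, by
   construction). Expanding `h'(x) = Σ_l b_l φ_l(x)` gives a
   scalar-on-function regression with design entries `⟨φ_l, W_k⟩`
   (`fit_sof()`) or its mean-exposure approximation `φ_l(x̄_k)`
   (`fit_sos()`), solved in closed form
   `b̂ = (XᵀΣ⁻¹X + λR)⁻¹XᵀΣ⁻¹β̂` with optional roughness penalty tuned by
   GCV (`select_lambda_gcv()`). `linearity_q_test()` is Cochran's Q across
   the stratum ratios.

3. **Change-point analysis.** Writing `h'(x) = b₀ + Σ_p b_p 1{x ≥ t_p}`
   over a dense candidate grid turns shape estimation into sparse
   regression on exact tail masses `∫_{t_p}^∞ W_k`
   (`build_changepoint_design()`), fitted by a from-scratch
   Sum-of-Single-Effects procedure (`susie_changepoint()`): iterative
   Bayesian stepwise selection over `L` single effects with per-effect
   prior-variance profiling, yielding posterior inclusion probabilities,
   credible sets (`credible_set()`, `changepoint_summary()`),
   counterfactual predictions (`counterfactual_predict()`), and a posterior
   effect curve with credible band (`posterior_effect_curve()`).

A simulation module (`scenario_spec()`, `generate_iv_data()`), oracle
control-function and IV-regression comparators, and a benchmarking harness
(`run_benchmark()`) reproduce the validation study designs. The methods
vignette (`vignettes/stratified-nonlinear-iv.Rmd`) documents the model,
conventions, and limitations.

## Worked example

Simulated one-change-point data (lognormal exposure, true threshold at
2.5, instrument R² ≈ 0.003, n = 50,000):

```r
library(sssiv)
ds <- generate_iv_data(scenario_spec("III", scenario = 3, effect_case = 2,
                                     n = 50000, seed = 7))
res <- run_pipeline(ds$data, method = "doubly_ranked", K = 100,
                    model = "changepoint", candidate_style = "left95",
                    L = 10, seed = 7)
res
#> <sss_pipeline>
#>   strata: doubly_ranked, K = 100
#>   linearity Q = 434.654 (df 99), p = 1.37e-43
#>   change-point model: L* = 1 detected effect(s)
changepoint_summary(res$fit)
#>   effect     mode     mean interval_lo interval_hi intercept_pip cs_size
#> 1      1 2.596933 2.538364    2.388759    2.724878  4.906468e-75       3
```

Reading the output: the Q test rejects a constant intensity (p ≈ 1e-43), a
single change-point is detected (`L* = 1` of the `L = 10` allowed), its
posterior mode 2.597 sits near the true threshold 2.5 with a 95% credible
interval of (2.39, 2.72), and essentially no posterior mass falls on the
intercept (global-linear) slot. `res$curve` holds the posterior effect
curve `h(x)` with its pointwise 95% credible band, anchored at `h(0) = 0`.

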