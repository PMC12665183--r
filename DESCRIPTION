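Package: sssiv
Title: Stratification-Based Instrumental Variable Analysis of Nonlinear Causal Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for nonlinear causal effect analysis with a single (possibly
    weak or binary) instrumental variable, as used in nonlinear Mendelian
    randomization. The sample is partitioned into collider-robust strata by the
    residual (prediction) or doubly-ranked (matching) method; stratum-specific
    Wald ratios and exactly-integrated step weight functions are combined in
    scalar-on-function or scalar-on-scalar regressions for the effect intensity
    h'(x); and a change-point representation of h'(x) is fitted with a
    Sum-of-Single-Effects Bayesian procedure to detect change-points, form
    credible sets, and reconstruct the effect curve with uncertainty. Includes
    a simulation module emulating weak-instrument study designs, oracle
    comparator estimators, and a benchmarking harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
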