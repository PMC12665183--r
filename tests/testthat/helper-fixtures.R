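# shared fixtures, built in code at test time

# small stratified summaries object from a seeded weak-instrument draw
make_summaries <- function(seed = 11L, n = 2000L, K = 10L,
                           part = "I", scenario = 1L, effect_case = NULL) {
  ds <- generate_iv_data(scenario_spec(part, scenario,
                                       effect_case = effect_case,
                                       n = n, seed = seed))
  strata <- doubly_ranked_stratify(ds$data, K)
  suppressWarnings(stratum_summaries(strata))
}

# the 4-point toy stratum of the weight-function examples
toy_weight <- function() estimate_weight_function(c(0, 0, 1, 1), c(1, 2, 3, 4))

# strong-instrument summaries where every stratum is well identified
make_strong_summaries <- function(seed = 4L, n = 3000L, K = 6L) {
  set.seed(seed)
  Z <- rnorm(n)
  U <- rnorm(n)
  X <- Z + U + rnorm(n)
  Y <- X + U + rnorm(n)
  strata <- doubly_ranked_stratify(data.frame(Z = Z, X = X, Y = Y), K)
  suppressWarnings(stratum_summaries(strata))
}

# brute-force single-effect marginal likelihood: y ~ N(0, s0 X_j X_j' + I)
# enumerated per candidate column (independent oracle for the SER posterior)
enumerate_ser_pip <- function(Xw, yw, s0, prior_pi) {
  n <- length(yw)
  logliks <- vapply(seq_len(ncol(Xw)), function(j) {
    S <- s0 * tcrossprod(Xw[, j]) + diag(n)
    -0.5 * (n * log(2 * pi) + as.numeric(determinant(S)$modulus) +
              drop(crossprod(yw, solve(S, yw))))
  }, numeric(1))
  lw <- log(prior_pi) + logliks
  w <- exp(lw - max(lw))
  w / sum(w)
}
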