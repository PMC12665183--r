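test_that("scalar-on-function design uses exact inner products", {
  su <- make_strong_summaries()
  des <- build_sof_design(su, basis_spec("polynomial", degree = 1))
  # <1, W_k> = 1 for every stratum by weight normalization
  expect_equal(des[, 1], rep(1, su$K), tolerance = 1e-12)
  # <x, W_k> is the weight-function mean, close to the stratum mean
  expect_equal(des[, 2], su$summaries$xbar, tolerance = 0.25)

  # toy weight: <x, W> = 0.25*1.5 + 0.5*2.5 + 0.25*3.5 = 2.5 exactly
  expect_equal(wf_moment(toy_weight(), 1), 2.5)
  # indicator inner products are tail masses: in [0,1], nonincreasing in t
  ts <- seq(0, 5, by = 0.5)
  tails <- wf_tail(toy_weight(), ts)
  expect_true(all(tails >= 0 & tails <= 1))
  expect_true(all(diff(tails) <= 0))
})

test_that("unpenalized single-constant fit collapses to the IVW mean", {
  su <- make_strong_summaries()
  fit <- fit_sof(su, basis_spec("polynomial", degree = 0), lambda = 0)
  tab <- su$summaries
  w <- 1 / tab$se_beta^2
  expect_equal(fit$b_hat, sum(w * tab$beta_hat) / sum(w), tolerance = 1e-12)
})

test_that("SoF closed form equals an independent generalized-least-squares solve", {
  # fixed 5-stratum skeleton with known design and variances
  X <- cbind(1, c(-2, -1, 0, 1, 2), c(4, 1, 0, 1, 4))
  se <- c(0.5, 1, 2, 1, 0.5)
  beta <- c(3.9, 1.1, 0.2, 2.9, 8.1)
  fit <- sssiv:::fit_weighted_basis(X, beta, se,
                                    basis_spec("polynomial", degree = 2),
                                    lambda = 0)
  # independently coded GLS via explicit weighted normal equations
  W <- diag(1 / se^2)
  b_oracle <- solve(t(X) %*% W %*% X, t(X) %*% W %*% beta)
  expect_equal(fit$b_hat, drop(b_oracle), tolerance = 1e-10)
  expect_equal(fit$cov_b, solve(t(X) %*% W %*% X), tolerance = 1e-10)
})

test_that("a large penalty shrinks the intensity toward the penalty null space", {
  su <- make_strong_summaries()
  basis <- basis_spec("polynomial", degree = 3, range = c(-5, 5))
  fit <- fit_sof(su, basis, lambda = 1e9, m = 1)
  grid <- seq(-2, 2, 0.5)
  hp <- effect_curve(fit, grid)$h_prime
  expect_lt(max(hp) - min(hp), 0.05)   # m = 1 null space: constants
})

test_that("GCV obeys the trace identity and matches brute-force evaluation", {
  su <- make_strong_summaries()
  basis <- basis_spec("polynomial", degree = 2, range = c(-6, 6))
  sel <- select_lambda_gcv(su, basis, m = 2, lambda_grid = c(0, 0.1, 1, 10, 100))
  tab <- sel$table
  # tr(H_0) equals the number of basis functions for a full-rank design
  expect_equal(tab$trace[tab$lambda == 0], 3, tolerance = 1e-8)
  # brute-force per-lambda recomputation
  des <- build_sof_design(su, basis)
  R <- basis_penalty(basis, 2, range = c(-6, 6))
  w <- 1 / su$summaries$se_beta
  Xw <- des * w; yw <- su$summaries$beta_hat * w
  K <- nrow(des)
  for (i in seq_len(nrow(tab))) {
    H <- Xw %*% solve(crossprod(Xw) + tab$lambda[i] * R) %*% t(Xw)
    sse <- sum((yw - H %*% yw)^2)
    gcv <- (K / (K - sum(diag(H)))) * sse / (K - sum(diag(H)))
    expect_equal(tab$gcv[i], gcv, tolerance = 1e-10)
  }
  # GCV-selected fit lies between the unpenalized and fully shrunk extremes
  sse_for <- function(lam) {
    f <- fit_sof(su, basis, lambda = lam, m = 2)
    sum(((su$summaries$beta_hat - des %*% f$b_hat) * w)^2)
  }
  expect_gte(sse_for(sel$lambda) + 1e-10, sse_for(0))
  expect_lte(sse_for(sel$lambda), sse_for(1e12) + 1e-10)
  # single-candidate grid returns that candidate
  expect_equal(select_lambda_gcv(su, basis, lambda_grid = 0.5)$lambda, 0.5)
})

test_that("scalar-on-scalar fit handles constant responses and approaches SoF for many strata", {
  su <- make_strong_summaries()
  su$summaries$beta_hat <- rep(2.5, su$K)
  su$summaries$se_beta <- rep(1, su$K)
  fit <- fit_sos(su, basis_spec("polynomial", degree = 1))
  expect_equal(fit$b_hat, c(2.5, 0), tolerance = 1e-10)

  # narrow-stratum limit: with noise-free parametric weights the SoF inner
  # products converge to the basis evaluated at the stratum means as strata
  # narrow (<x, W_k> = xbar_k exactly; <x^2, W_k> = xbar_k^2 + s_k^2)
  gap <- function(K) {
    ds <- generate_iv_data(scenario_spec("I", 3, n = 20000, seed = 12))
    st <- doubly_ranked_stratify(ds$data, K)
    s <- suppressWarnings(stratum_summaries(st, weights = "parametric"))
    b <- basis_spec("polynomial", degree = 2)
    max(abs(build_sof_design(s, b) - basis_eval(b, s$summaries$xbar)))
  }
  expect_lt(gap(40), gap(4) * 0.6)
})

test_that("effect curves integrate the intensity and anchor at zero", {
  b <- basis_spec("polynomial", degree = 0)
  fit <- structure(list(b_hat = 1, cov_b = matrix(0.01), basis = b,
                        lambda = 0, model = "sof"), class = "sss_fit")
  ec <- effect_curve(fit, seq(-2, 2, 0.5))
  expect_equal(ec$h, ec$grid)          # h(x) = x when h' = 1
  expect_equal(ec$h_prime, rep(1, 9))
  expect_equal(ec$h[ec$grid == 0], 0)

  # change-point basis: coefficients (0, 1) at t = 2 give h(x) = (x - 2)_+
  cb <- basis_spec("changepoint", candidates = 2)
  fit2 <- structure(list(b_hat = c(0, 1), cov_b = diag(2) * 0, basis = cb,
                         lambda = 0, model = "sof"), class = "sss_fit")
  g <- seq(0, 4, 0.5)
  ec2 <- effect_curve(fit2, g)
  expect_equal(ec2$h, pmax(g - 2, 0))
  expect_equal(ec2$h[g == 0], 0)
  # negative-threshold hinge is anchored too: h(0) = (0-t)_+ - (-t)_+ = 0
  cbn <- basis_spec("changepoint", candidates = -1)
  fit3 <- structure(list(b_hat = c(0, 1), cov_b = diag(2) * 0, basis = cbn,
                         lambda = 0, model = "sof"), class = "sss_fit")
  ec3 <- effect_curve(fit3, c(-2, 0, 2))
  expect_equal(ec3$h, pmax(c(-2, 0, 2) + 1, 0) - 1)   # (x+1)_+ - (0+1)_+
})

test_that("linear intensity fits recover the centre and agree across SoS and SoF", {
  # under the quadratic effect the fitted intensity is exact at the exposure
  # centre (hhat'(0) ~ h'(0) = 1); away from the centre the weak instrument
  # attenuates the identified slope, which both regressions share (this is
  # what the large outer-quantile benchmark MSEs of the intensity reflect)
  su <- make_summaries(seed = 77, n = 50000, K = 100, part = "II",
                       effect_case = "linear_quadratic")
  fit_s <- fit_sos(su, basis_spec("polynomial", degree = 1))
  fit_f <- fit_sof(su, basis_spec("polynomial", degree = 1))
  expect_equal(fit_s$b_hat[1], 1, tolerance = 0.3)
  expect_equal(fit_f$b_hat[1], 1, tolerance = 0.3)
  expect_gt(fit_s$b_hat[2], 0.5)          # slope sign and order of magnitude
  expect_gt(fit_f$b_hat[2], 0.5)
  expect_lt(max(abs(fit_s$b_hat - fit_f$b_hat)), 0.2)
})

test_that("B-spline designs integrate exactly against step weights", {
  su <- make_strong_summaries()
  rng <- range(sapply(su$weights, function(w) range(w$breaks)))
  basis <- basis_spec("bspline", degree = 3, knots = c(-1, 0, 1), range = rng)
  des <- build_sof_design(su, basis)
  # B-splines sum to one pointwise, so design rows sum to the weight integral
  expect_equal(rowSums(des), rep(1, su$K), tolerance = 1e-8)
  R <- basis_penalty(basis, 2)
  expect_equal(R, t(R), tolerance = 1e-10)
  expect_true(all(eigen(R, symmetric = TRUE, only.values = TRUE)$values > -1e-8))
  fit <- fit_sof(su, basis, lambda = "gcv")
  ec <- effect_curve(fit, seq(rng[1] + 0.1, rng[2] - 0.1, length.out = 30))
  expect_equal(ec$h[which.min(abs(ec$grid))], 0, tolerance = 0.15)
})
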