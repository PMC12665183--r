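test_that("change-point design columns are tail masses with an intercept slot", {
  su <- make_strong_summaries()
  lo <- min(sapply(su$weights, function(w) w$breaks[1]))
  hi <- max(sapply(su$weights, function(w) max(w$breaks)))
  des <- suppressMessages(
    build_changepoint_design(su, c(lo - 1, 0, hi + 1)))
  D <- des$design
  expect_equal(D[, 1], rep(1, su$K))
  expect_equal(D[, 2], rep(1, su$K))   # below every support: full tail mass
  expect_equal(D[, 4], rep(0, su$K))   # above every support
  expect_true(all(D >= 0 & D <= 1))
  for (k in seq_len(su$K)) expect_true(all(diff(D[k, -1]) <= 1e-12))
  expect_true(all(c(2, 4) %in% des$flagged))

  # toy weight, t = 2.5: tail = 0.5*0.5 + 0.25*1 = 0.5
  su2 <- su
  su2$weights <- rep(list(toy_weight()), su$K)
  d2 <- suppressMessages(build_changepoint_design(su2, 2.5))
  expect_equal(d2$design[, 2], rep(0.5, su$K))
})

test_that("single-effect posterior matches brute-force marginal-likelihood enumeration", {
  set.seed(42)
  for (P1 in 2:3) {
    Xw <- matrix(rnorm(12 * P1), 12, P1)
    yw <- Xw[, 1] * 0.8 + rnorm(12)
    prior <- rep(1 / P1, P1)
    for (s0 in c(0.3, 1, 4)) {
      sep <- single_effect_posterior(Xw, yw, s0, prior)
      expect_equal(sum(sep$pip), 1, tolerance = 1e-12)
      oracle <- enumerate_ser_pip(Xw, yw, s0, prior)
      expect_equal(sep$pip, oracle, tolerance = 1e-10)
    }
  }
})

test_that("degenerate single-effect priors behave as limits", {
  Xw <- cbind(1, c(0, 0, 1, 1))
  yw <- c(0.1, -0.1, 1, 1.2)
  sep0 <- single_effect_posterior(Xw, yw, 0, c(0.5, 0.5))
  expect_equal(sep0$pip, c(0.5, 0.5))     # point-mass prior: posterior = prior
  expect_equal(sep0$mu, c(0, 0))
  # a column aligned with the response and tiny noise dominates
  Xw2 <- cbind(c(1, -1, 1, -1), yw / sqrt(sum(yw^2)))
  sep2 <- single_effect_posterior(Xw2 * 50, yw * 50, 1, c(0.5, 0.5))
  expect_gt(sep2$pip[2], 0.999)
})

test_that("credible sets are smallest descending-PIP prefixes", {
  expect_equal(credible_set(c(0.97, 0.02, 0.01)), 1L)
  expect_equal(credible_set(rep(1 / 20, 20)), 1:19)
  expect_equal(credible_set(c(0.5, 0.3, 0.2)), 1:3)
  expect_equal(credible_set(c(0.2, 0.5, 0.3), level = 0.6), 2:3)
})

test_that("IBSS with L = 1 reduces to the profiled single-effect model", {
  su <- make_strong_summaries()
  des <- suppressMessages(build_changepoint_design(su, c(-1, 0, 1)))
  fit <- susie_changepoint(des, L = 1)
  w <- 1 / des$se
  st <- sssiv:::ser_stats(des$design * w, des$response * w)
  s0 <- sssiv:::profile_sigma0sq(st, rep(1 / 4, 4))
  sep <- sssiv:::ser_posterior(st, s0, rep(1 / 4, 4))
  expect_equal(drop(fit$pip), sep$pip, tolerance = 1e-12)
  expect_equal(drop(fit$mu), sep$mu, tolerance = 1e-12)
})

test_that("a pure linear effect loads on the intercept slot with one active effect", {
  # response exactly proportional to the intercept column, tight errors
  su <- make_strong_summaries()
  des <- suppressMessages(build_changepoint_design(su, c(-1, 0, 1)))
  des$response <- rep(2, su$K)
  des$se <- rep(0.01, su$K)
  fit <- susie_changepoint(des, L = 5)
  expect_equal(fit$L_star, 1)
  act <- which(fit$active)
  expect_gt(fit$pip[act, 1], 0.95)
  expect_equal(sum(fit$b_post), 2, tolerance = 0.05)
  # pip rows always sum to one, including inert effects
  expect_equal(rowSums(fit$pip), rep(1, 5), tolerance = 1e-10)
})

test_that("counterfactual contrasts satisfy the hinge identities", {
  su <- make_strong_summaries()
  des <- suppressMessages(build_changepoint_design(su, c(-1, 2)))
  fit <- susie_changepoint(des, L = 2)
  # f(3; 1, 2) = (3-2)_+ - (1-2)_+ = 1
  Fm <- sssiv:::cp_contrast(3, 1, c(-1, 2))
  expect_equal(Fm[1, ], c(2, 2, 1))   # intercept slot: x* - x0
  # x* = X_i: no intervention, prediction returns the observed outcome
  d <- data.frame(X = c(0.5), Y = c(7))
  expect_equal(counterfactual_predict(fit, d, 0.5), 7)
  # single certain effect: Yhat = Y + b * f(x*; X, t)
  fit1 <- fit
  fit1$b_post <- c(0, 0, 3)
  expect_equal(counterfactual_predict(fit1, data.frame(X = 1, Y = 2), 4),
               2 + 3 * (pmax(4 - 2, 0) - pmax(1 - 2, 0)))
})

test_that("posterior effect curves anchor at zero and honor certain effects", {
  su <- make_strong_summaries()
  des <- suppressMessages(build_changepoint_design(su, c(-1, 0, 1)))
  fit <- susie_changepoint(des, L = 2)
  ec <- posterior_effect_curve(fit, c(-1, 0, 2), n_draws = 1000)
  i0 <- which(ec$grid == 0)
  expect_equal(ec$h[i0], 0)
  expect_equal(ec$lower[i0], 0)
  expect_equal(ec$upper[i0], 0)

  # one certain effect at t = 2 with unit size: h(x) = (x - 2)_+, zero band
  fitc <- fit
  fitc$candidates <- 2
  fitc$L <- 1
  fitc$active <- TRUE
  fitc$pip <- matrix(c(0, 1), 1)
  fitc$mu <- matrix(c(0, 1), 1)
  fitc$sigma <- matrix(0, 1, 2)
  fitc$b_post <- c(0, 1)
  g <- seq(0, 4, 0.5)
  ec2 <- posterior_effect_curve(fitc, g, n_draws = 1000)
  expect_equal(ec2$h, pmax(g - 2, 0))
  expect_equal(ec2$lower, ec2$upper)
  expect_equal(ec2$lower, pmax(g - 2, 0))
})

test_that("sampled credible band matches the analytic two-component mixture", {
  # one effect, two candidates: the posterior of h(x*) is a two-component
  # normal mixture whose quantiles invert the mixture CDF
  cand <- c(1, 3)
  pip <- c(0.6, 0.4); mu <- c(0.5, 2); sig <- c(0.2, 0.3)
  fit <- structure(list(candidates = cand, L = 1, active = TRUE,
                        pip = matrix(pip, 1), mu = matrix(mu, 1),
                        sigma = matrix(sig, 1),
                        b_post = pip * mu), class = "sss_susie")
  x_star <- 4
  f <- c(pmax(x_star - cand[1], 0), pmax(x_star - cand[2], 0))  # (3, 1)
  mix_cdf <- function(q) pip[1] * pnorm(q, f[1] * mu[1], f[1] * sig[1]) +
    pip[2] * pnorm(q, f[2] * mu[2], f[2] * sig[2])
  q_lo <- uniroot(function(q) mix_cdf(q) - 0.025, c(-10, 20), tol = 1e-10)$root
  q_hi <- uniroot(function(q) mix_cdf(q) - 0.975, c(-10, 20), tol = 1e-10)$root
  set.seed(99)
  # intercept slot unused: candidates enter at slots 2:3
  fit$pip <- matrix(c(0, pip), 1); fit$mu <- matrix(c(0, mu), 1)
  fit$sigma <- matrix(c(0, sig), 1); fit$b_post <- c(0, pip * mu)
  ec <- posterior_effect_curve(fit, x_star, n_draws = 200000)
  expect_equal(ec$lower, q_lo, tolerance = 0.02)
  expect_equal(ec$upper, q_hi, tolerance = 0.02)
  expect_equal(ec$h, sum(pip * mu * f), tolerance = 1e-10)
})

test_that("one-change-point fixtures yield a single credible set at the truth, robust to L", {
  ds <- generate_iv_data(scenario_spec("III", 1, effect_case = 2,
                                       n = 50000, seed = 31))
  st <- doubly_ranked_stratify(ds$data, 100)
  su <- suppressWarnings(stratum_summaries(st))
  cand <- changepoint_candidates(ds$data$X, "middle90")
  des <- suppressMessages(build_changepoint_design(su, cand))
  modes <- sapply(c(5, 10, 20), function(L) {
    fit <- suppressWarnings(susie_changepoint(des, L = L))
    cs <- changepoint_summary(fit)
    c(fit$L_star, cs$mode[1])
  })
  expect_true(all(modes[1, ] == modes[1, 1]))        # L_star insensitive to L
  expect_lt(max(abs(modes[2, ] - modes[2, 1])), 1e-8)
  expect_lt(abs(modes[2, 1]), 0.8)                   # mode near the true 0
})
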