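#' Default change-point candidate grids
#'
#' For roughly symmetric (normal-like) exposures, candidates are the middle
#' 90 percent sample quantiles (percentiles 5 to 95); for right-skewed
#' (lognormal-like) exposures, the left 95 percent quantiles including the
#' minimum-side percentile 0. Both grids step by one percentile.
#'
#' @param x exposure values.
#' @param style `"middle90"` or `"left95"`.
#' @return sorted numeric vector of distinct candidate thresholds.
#' @export
changepoint_candidates <- function(x, style = c("middle90", "left95")) {
  style <- match.arg(style)
  probs <- switch(style, middle90 = 5:95 / 100, left95 = 0:95 / 100)
  sort(unique(unname(stats::quantile(x, probs))))
}

#' Change-point design from stratum weight functions
#'
#' Builds the K x (P + 1) design of the change-point model
#' `beta_k = b0 + sum_p b_p int_{t_p}^Inf W_k(x) dx + eps_k`: column 1 is the
#' intercept slot (all ones, the potential global linear effect), and column
#' p + 1 holds the exact tail mass of stratum k's step weight beyond
#' candidate t_p. Tail masses lie in [0, 1] and are nonincreasing in p within
#' each row. Candidates outside every weight support give degenerate all-0 or
#' all-1 columns; these are kept but flagged.
#'
#' @param summaries an `sss_summaries` object.
#' @param candidates sorted candidate thresholds.
#' @return an object of class `sss_cp_design`: list with `design`,
#'   `candidates`, `response` (Wald ratios), `se` (their standard errors) and
#'   `flagged` (indices of degenerate candidate columns).
#' @export
build_changepoint_design <- function(summaries, candidates) {
  stopifnot(inherits(summaries, "sss_summaries"))
  if (is.unsorted(candidates, strictly = TRUE))
    stop("candidates must be strictly increasing")
  K <- summaries$K
  P <- length(candidates)
  D <- matrix(NA_real_, K, P + 1L)
  D[, 1L] <- 1
  for (k in seq_len(K)) D[k, -1L] <- wf_tail(summaries$weights[[k]], candidates)
  flagged <- 1L + which(apply(D[, -1L, drop = FALSE], 2L,
                              function(col) all(col == 0) || all(col == 1)))
  if (length(flagged))
    message(length(flagged),
            " candidate column(s) degenerate (outside all weight supports)")
  structure(list(design = D, candidates = candidates,
                 response = summaries$summaries$beta_hat,
                 se = summaries$summaries$se_beta,
                 flagged = flagged),
            class = "sss_cp_design")
}

#' Posterior of a single-effect Bayesian regression
#'
#' For a whitened system (response and design columns premultiplied by the
#' inverse error standard deviations, so errors are unit normal), computes
#' for each column p the Bayesian simple-regression posterior under the
#' single-effect prior `b = gamma b`, `b ~ N(0, sigma0sq)`,
#' `gamma ~ Multinomial(1, prior_pi)`:
#' posterior variance `sigma*^2 = (s_p^-2 + sigma0sq^-1)^-1`, posterior mean
#' `mu* = sigma*^2 s_p^-2 bhat_p`, and inclusion probabilities
#' `pip_p \propto prior_pi_p BF_p` with the exact Gaussian Bayes factor,
#' evaluated in log space.
#'
#' @param Xw whitened design matrix.
#' @param yw whitened response vector.
#' @param sigma0sq prior effect variance (>= 0; at 0 the posterior collapses
#'   to the prior with zero means).
#' @param prior_pi prior inclusion probabilities (default uniform).
#' @return list with `pip`, `mu`, `sigma` (vectors over columns) and
#'   `loglik`, the log marginal likelihood of the single-effect model up to
#'   the null-model constant.
#' @export
single_effect_posterior <- function(Xw, yw, sigma0sq,
                                    prior_pi = rep(1 / ncol(Xw), ncol(Xw))) {
  stopifnot(sigma0sq >= 0, length(prior_pi) == ncol(Xw))
  ser_posterior(ser_stats(Xw, yw), sigma0sq, prior_pi)
}

# per-column weighted-least-squares sufficient statistics of the whitened
# single-effect regression; computed once and reused across sigma0^2 values
ser_stats <- function(Xw, yw) {
  d <- colSums(Xw^2)
  ok <- d > 0
  bhat <- numeric(length(d)); s2 <- rep(Inf, length(d))
  if (any(ok)) {
    bhat[ok] <- drop(crossprod(Xw[, ok, drop = FALSE], yw)) / d[ok]
    s2[ok] <- 1 / d[ok]
  }
  list(bhat = bhat, s2 = s2, ok = ok)
}

ser_posterior <- function(st, sigma0sq, prior_pi) {
  P1 <- length(st$bhat)
  if (sigma0sq == 0)
    return(list(pip = prior_pi, mu = numeric(P1), sigma = numeric(P1),
                loglik = 0))
  ok <- st$ok; s2 <- st$s2; bhat <- st$bhat
  post_var <- sigma0sq * s2 / (sigma0sq + s2)       # -> sigma0sq when s2 = Inf
  post_var[!ok] <- sigma0sq
  mu <- ifelse(ok, post_var * bhat / s2, 0)
  lbf <- ifelse(ok,
                0.5 * log(s2 / (s2 + sigma0sq)) +
                  0.5 * (bhat^2 / s2) * sigma0sq / (sigma0sq + s2),
                0)
  lw <- log(prior_pi) + lbf
  mx <- max(lw)
  pip <- exp(lw - mx); pip <- pip / sum(pip)
  list(pip = pip, mu = mu, sigma = sqrt(post_var),
       loglik = mx + log(sum(exp(lw - mx))))
}

# profile sigma0^2 for one single-effect update by maximizing the log
# marginal likelihood over log sigma0^2; returns 0 when the null is at least
# as good (inert effect).
profile_sigma0sq <- function(st, prior_pi) {
  obj <- function(lv) ser_posterior(st, exp(lv), prior_pi)$loglik
  opt <- stats::optimize(obj, interval = c(-30, 15), maximum = TRUE)
  if (opt$objective > 0) exp(opt$maximum) else 0
}

#' Sum-of-Single-Effects fit of the change-point model
#'
#' Fits the sparse regression `beta = X b + eps`, `eps ~ N(0, Sigma)` with
#' `b = sum_l b_l` and each `b_l` a single effect, by Iterative Bayesian
#' Stepwise Selection (IBSS): cycling over effects l = 1..L, subtracting the
#' expected contribution of all other effects from the response, and updating
#' effect l by [single_effect_posterior()] on the residualized system. The
#' heteroscedastic system is premultiplied by `Sigma^{-1/2}` (the standard
#' errors are known from the stratum summaries, not estimated), reducing to a
#' unit-variance problem. Each effect's prior variance `sigma0sq` is
#' re-profiled every pass by maximizing its single-effect marginal
#' likelihood; effects whose profiled variance stays below
#' `1e-8 * var(whitened response)` are inert and excluded from the effective
#' count `L_star`.
#'
#' @param design an `sss_cp_design` from [build_changepoint_design()], or a
#'   plain design matrix (then `response` and `se` must be supplied).
#' @param L maximum number of effects (default 10).
#' @param prior_pi prior inclusion probabilities (default uniform over the
#'   P + 1 candidate slots).
#' @param tol convergence tolerance on the posterior-mean coefficient vector
#'   (default 1e-6).
#' @param max_iter maximum IBSS passes (default 100; non-convergence returns
#'   the last iterate with a warning).
#' @param response,se response vector and its standard errors when `design`
#'   is a plain matrix.
#' @return an object of class `sss_susie`: matrices `pip`, `mu`, `sigma`
#'   (L x (P+1)), `sigma0sq` and `active` per effect, `L_star`, `b_post`
#'   (posterior-mean coefficient vector), `candidates`, credible sets, and
#'   convergence information.
#' @export
susie_changepoint <- function(design, L = 10L, prior_pi = NULL, tol = 1e-6,
                              max_iter = 100L, response = NULL, se = NULL) {
  if (inherits(design, "sss_cp_design")) {
    candidates <- design$candidates
    response <- design$response
    se <- design$se
    X <- design$design
  } else {
    X <- as.matrix(design)
    candidates <- attr(design, "candidates")
    if (is.null(response) || is.null(se))
      stop("plain-matrix design requires 'response' and 'se'")
  }
  L <- as.integer(L)
  stopifnot(L >= 1L, nrow(X) == length(response), length(se) == length(response),
            all(se > 0))
  P1 <- ncol(X)
  if (is.null(prior_pi)) prior_pi <- rep(1 / P1, P1)
  stopifnot(length(prior_pi) == P1, all(prior_pi >= 0))
  prior_pi <- prior_pi / sum(prior_pi)

  w <- 1 / se
  Xw <- X * w
  yw <- response * w
  inert_tol <- 1e-8 * stats::var(yw)

  b_l <- matrix(0, L, P1)        # per-effect posterior-mean coefficients
  pip <- matrix(rep(prior_pi, each = L), L, P1)
  mu <- matrix(0, L, P1)
  sig <- matrix(0, L, P1)
  s0 <- rep(stats::var(yw), L)
  fitted_total <- drop(Xw %*% colSums(b_l))
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    b_old <- colSums(b_l)
    for (l in seq_len(L)) {
      r_l <- yw - fitted_total + drop(Xw %*% b_l[l, ])
      st <- ser_stats(Xw, r_l)
      s0[l] <- profile_sigma0sq(st, prior_pi)
      sep <- ser_posterior(st, s0[l], prior_pi)
      new_b <- sep$pip * sep$mu
      fitted_total <- fitted_total + drop(Xw %*% (new_b - b_l[l, ]))
      b_l[l, ] <- new_b
      pip[l, ] <- sep$pip
      mu[l, ] <- sep$mu
      sig[l, ] <- sep$sigma
    }
    if (max(abs(colSums(b_l) - b_old)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("IBSS did not converge in ", max_iter, " passes; returning last iterate")
  active <- s0 > inert_tol      # strict: a profiled zero variance is inert
                                # even for a degenerate constant response
  cs <- lapply(seq_len(L), function(l) credible_set(pip[l, ]))
  structure(list(pip = pip, mu = mu, sigma = sig, sigma0sq = s0,
                 active = active, L = L, L_star = sum(active),
                 b_post = colSums(b_l), prior_pi = prior_pi,
                 candidates = candidates, credible_sets = cs,
                 response = response, se = se, design = X,
                 converged = converged, n_iter = it),
            class = "sss_susie")
}

#' @export
print.sss_susie <- function(x, ...) {
  cat(sprintf("<sss_susie> L = %d effects, L* = %d active, %sconverged in %d passes\n",
              x$L, x$L_star, if (x$converged) "" else "NOT ", x$n_iter))
  if (x$L_star > 0 && !is.null(x$candidates)) {
    s <- changepoint_summary(x)
    if (nrow(s)) {
      cat("detected change-points:\n")
      print(s, row.names = FALSE)
    }
  }
  invisible(x)
}

#' Level-95 credible set from a row of posterior inclusion probabilities
#'
#' The smallest prefix of candidates sorted by descending inclusion
#' probability whose cumulative mass reaches the level; ties are broken by
#' candidate order.
#'
#' @param pip vector of posterior inclusion probabilities (sums to 1).
#' @param level nominal coverage (default 0.95).
#' @return integer vector of candidate-slot indices, in ascending order.
#' @export
credible_set <- function(pip, level = 0.95) {
  stopifnot(abs(sum(pip) - 1) < 1e-6)
  o <- order(-pip)              # stable: ties keep candidate order
  m <- which(cumsum(pip[o]) >= level - 1e-12)[1L]
  sort(o[seq_len(m)])
}

#' Point and interval summaries of detected change-points
#'
#' For each active effect, summarises the posterior over the change-point
#' *location*: the inclusion probabilities over the non-intercept candidate
#' slots are renormalized, giving the posterior mode and mean of the
#' threshold, a central two-sided interval holding `level` cumulative
#' posterior mass over the ordered candidates (`interval_lo`, `interval_hi`),
#' and the descending-PIP credible set size. `intercept_pip` reports the mass
#' on the intercept (global linear) slot before renormalization.
#'
#' @param fit an `sss_susie` fit with candidate values.
#' @param level credible level (default 0.95).
#' @return data frame with one row per active effect.
#' @export
changepoint_summary <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "sss_susie"), !is.null(fit$candidates))
  rows <- lapply(which(fit$active), function(l) {
    p <- fit$pip[l, ]
    pc <- p[-1L]
    if (sum(pc) <= 0) return(NULL)
    pc <- pc / sum(pc)
    cum <- cumsum(pc)
    lo <- fit$candidates[which(cum >= (1 - level) / 2)[1L]]
    hi <- fit$candidates[which(cum >= 1 - (1 - level) / 2)[1L]]
    data.frame(effect = l,
               mode = fit$candidates[which.max(pc)],
               mean = sum(pc * fit$candidates),
               interval_lo = lo, interval_hi = hi,
               intercept_pip = p[1L],
               cs_size = length(credible_set(p, level)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(effect = integer(0), mode = numeric(0),
                      mean = numeric(0), interval_lo = numeric(0),
                      interval_hi = numeric(0), intercept_pip = numeric(0),
                      cs_size = integer(0))
  out
}

# partial counterfactual contrast f(x*; x0, t_p) = (x*-t)_+ - (x0-t)_+ for
# candidate slots; the intercept slot behaves as t0 = -Inf, i.e. x* - x0.
cp_contrast <- function(x_star, x0, candidates) {
  P1 <- length(candidates) + 1L
  out <- matrix(NA_real_, length(x0), P1)
  out[, 1L] <- x_star - x0
  for (p in seq_along(candidates)) {
    t <- candidates[p]
    out[, p + 1L] <- pmax(x_star - t, 0) - pmax(x0 - t, 0)
  }
  out
}

#' Posterior-mean counterfactual outcome predictions
#'
#' For each individual, predicts the outcome that would be observed if the
#' exposure were shifted from its observed value to `x_star`:
#' `Yhat_i(x*) = Y_i + sum_p f(x*; X_i, t_p) b_post_p`, where
#' `f(x*; X_i, t_p) = (x* - t_p)_+ - (X_i - t_p)_+` and the intercept slot
#' contributes the pure linear term `x* - X_i`.
#'
#' @param fit an `sss_susie` fit.
#' @param data data frame with columns `X` and `Y` on the same exposure
#'   scale as the fit.
#' @param x_star intervention exposure level (scalar).
#' @return numeric vector of per-individual predicted outcomes.
#' @export
counterfactual_predict <- function(fit, data, x_star) {
  stopifnot(inherits(fit, "sss_susie"), !is.null(fit$candidates),
            all(c("X", "Y") %in% names(data)), length(x_star) == 1L)
  Fm <- cp_contrast(x_star, data$X, fit$candidates)
  data$Y + drop(Fm %*% fit$b_post)
}

#' Posterior effect curve with credible band
#'
#' Point estimate `h(x) = [f(x; 0, t_p)]_p' b_post` (exactly 0 at x = 0) and
#' a pointwise credible band obtained by Monte-Carlo sampling from the
#' posterior: for each draw and each effect, a candidate slot is drawn from
#' that effect's inclusion probabilities and an effect size from the
#' conditional normal posterior; effect contributions are summed and the
#' band is formed from the draw quantiles at each grid point. Candidate
#' indices are drawn once per (draw, effect), so each sampled curve is
#' internally coherent.
#'
#' @param fit an `sss_susie` fit.
#' @param grid exposure grid.
#' @param n_draws posterior draws (default 10000, minimum 1000).
#' @param level band level (default 0.95).
#' @return a data frame of class `sss_effect_curve` with columns `grid`, `h`,
#'   `h_prime` (posterior-mean intensity), `lower`, `upper` and attribute
#'   `band_kind = "credible"`.
#' @export
posterior_effect_curve <- function(fit, grid, n_draws = 10000L, level = 0.95) {
  stopifnot(inherits(fit, "sss_susie"), !is.null(fit$candidates),
            n_draws >= 1000L)
  Fg <- cp_contrast_grid(grid, fit$candidates)
  h <- drop(Fg %*% fit$b_post)
  hp <- drop(cbind(1, outer(grid, fit$candidates, ">")) %*% fit$b_post)
  H <- matrix(0, length(grid), n_draws)
  for (l in seq_len(fit$L)) {
    if (!fit$active[l]) next
    pd <- sample.int(ncol(Fg), n_draws, replace = TRUE, prob = fit$pip[l, ])
    bd <- stats::rnorm(n_draws, fit$mu[l, pd], fit$sigma[l, pd])
    H <- H + sweep(Fg[, pd, drop = FALSE], 2L, bd, "*")
  }
  qs <- apply(H, 1L, stats::quantile,
              probs = c((1 - level) / 2, 1 - (1 - level) / 2))
  out <- data.frame(grid = grid, h = h, h_prime = hp,
                    lower = qs[1L, ], upper = qs[2L, ])
  attr(out, "band_kind") <- "credible"
  class(out) <- c("sss_effect_curve", "data.frame")
  out
}

# f(x; 0, t_p) for a grid of x values (rows) and candidate slots (columns)
cp_contrast_grid <- function(grid, candidates) {
  out <- cbind(grid,
               outer(grid, candidates,
                     function(x, t) pmax(x - t, 0) - pmax(-t, 0)))
  dimnames(out) <- NULL
  out
}
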