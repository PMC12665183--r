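#' Stratum-level Wald ratio
#'
#' The stratum IV estimate is the ratio of the instrument-outcome to
#' instrument-exposure association: beta = Cov(Z, Y) / Cov(Z, X), with sample
#' covariances (denominator n - 1). Under within-stratum exchangeability it
#' converges to the weighted average of the effect intensity h'(x) against the
#' stratum weight function.
#'
#' @param z,x,y instrument, exposure and outcome values within one stratum
#'   (at least 3 rows; Z must vary).
#' @return list with `alpha_hat` (Cov(Z,X)), `theta_hat` (Cov(Z,Y)),
#'   `beta_hat` (the ratio) and `weak` (TRUE when |alpha_hat| is below machine
#'   tolerance, in which case `beta_hat` is NA).
#' @export
wald_ratio <- function(z, x, y) {
  n <- length(z)
  stopifnot(length(x) == n, length(y) == n)
  if (n < 3L) stop("stratum has fewer than 3 rows")
  if (stats::sd(z) == 0) stop("constant instrument within stratum")
  alpha <- stats::cov(z, x)
  theta <- stats::cov(z, y)
  weak <- abs(alpha) < .Machine$double.eps * n * max(1, stats::sd(x)) * max(1, stats::sd(z))
  list(alpha_hat = alpha, theta_hat = theta,
       beta_hat = if (weak) NA_real_ else theta / alpha, weak = weak)
}

#' Delta-method standard error of a Wald ratio
#'
#' First order: `se(theta)/|alpha|`. Second order adds the uncertainty of the
#' instrument-exposure association:
#' `sqrt(se(theta)^2/alpha^2 + (theta/alpha)^2 * se(alpha)^2 / alpha^2)`.
#' Both are the standard inverse-variance-weighting error conventions; the
#' formulas are invariant to whether the associations are expressed as
#' covariances or as regression slopes, provided the standard errors are on
#' the same scale.
#'
#' @param se_theta standard error of the instrument-outcome association.
#' @param alpha_hat instrument-exposure association (nonzero).
#' @param order `"first"` or `"second"`.
#' @param theta_hat instrument-outcome association (needed for second order).
#' @param se_alpha standard error of `alpha_hat` (needed for second order).
#' @return the standard error of the Wald ratio.
#' @export
wald_se <- function(se_theta, alpha_hat, order = c("first", "second"),
                    theta_hat = NULL, se_alpha = NULL) {
  order <- match.arg(order)
  if (alpha_hat == 0) stop("alpha_hat must be nonzero")
  if (order == "first") return(se_theta / abs(alpha_hat))
  if (is.null(se_alpha) || is.null(theta_hat) || !is.finite(se_alpha))
    stop("second-order error requires theta_hat and a finite se_alpha")
  sqrt(se_theta^2 / alpha_hat^2 +
         (theta_hat / alpha_hat)^2 * se_alpha^2 / alpha_hat^2)
}

# classical slope and slope-se of the simple regression of v on z
slope_se <- function(z, v) {
  n <- length(z)
  zc <- z - mean(z)
  sxx <- sum(zc^2)
  slope <- sum(zc * v) / sxx
  res <- v - mean(v) - slope * zc
  se <- sqrt(sum(res^2) / (n - 2) / sxx)
  list(slope = slope, se = se)
}

#' Per-stratum IV summary statistics
#'
#' For each stratum: size, instrument-exposure and instrument-outcome
#' associations (sample covariances), Wald ratio, its standard error (first-
#' or second-order), the stratum exposure mean, and the estimated weight
#' function (empirical step function by default, or the normal parametric
#' form using only the stratum exposure mean and sd).
#'
#' The instrument-association standard errors entering the Wald-ratio error
#' are the classical slope standard errors of the within-stratum simple
#' regressions of Y on Z and X on Z, rescaled to the covariance scale (the
#' rescaling cancels in the ratio). Strata whose instrument-exposure
#' association has |t| < 2 are flagged weak; they trigger a warning and are
#' retained unless `drop_weak = TRUE`.
#'
#' @param strata an `sss_strata` object.
#' @param se_order `"first"` (default) or `"second"` Wald-ratio error.
#' @param weights `"empirical"` step-function estimate or `"parametric"`
#'   normal form.
#' @param drop_weak drop weak strata instead of retaining them.
#' @return an object of class `sss_summaries`: a list with `summaries`
#'   (data frame with columns k, n_k, alpha_hat, theta_hat, beta_hat,
#'   se_beta, xbar, weak) and `weights` (list of [weight_fn] per stratum).
#' @export
stratum_summaries <- function(strata, se_order = c("first", "second"),
                              weights = c("empirical", "parametric"),
                              drop_weak = FALSE) {
  se_order <- match.arg(se_order)
  weights <- match.arg(weights)
  stopifnot(inherits(strata, "sss_strata"))
  dat <- strata_data(strata)
  ks <- sort(unique(dat$stratum))
  rows <- vector("list", length(ks))
  wlist <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    d <- dat[dat$stratum == ks[i], , drop = FALSE]
    wr <- tryCatch(wald_ratio(d$Z, d$X, d$Y),
                   error = function(e) stop("stratum ", ks[i], ": ",
                                            conditionMessage(e), call. = FALSE))
    ry <- slope_se(d$Z, d$Y)
    rx <- slope_se(d$Z, d$X)
    vz <- stats::var(d$Z)
    se_theta <- ry$se * vz   # covariance-scale se, matching alpha/theta scale
    se_alpha <- rx$se * vz
    se_beta <- wald_se(se_theta, wr$alpha_hat, se_order,
                       theta_hat = wr$theta_hat, se_alpha = se_alpha)
    weak <- wr$weak || abs(rx$slope / rx$se) < 2
    rows[[i]] <- data.frame(k = ks[i], n_k = nrow(d),
                            alpha_hat = wr$alpha_hat, theta_hat = wr$theta_hat,
                            beta_hat = wr$beta_hat, se_beta = se_beta,
                            se_alpha = se_alpha, xbar = mean(d$X), weak = weak)
    wlist[[i]] <- switch(weights,
      empirical = estimate_weight_function(d$Z, d$X),
      parametric = parametric_weight_function(mean(d$X), stats::sd(d$X)))
  }
  tab <- do.call(rbind, rows)
  if (any(tab$weak)) {
    warning(sum(tab$weak), " weak stratum/strata (|t| of alpha_hat < 2)",
            if (drop_weak) "; dropped" else "; retained")
    if (drop_weak) {
      keep <- !tab$weak
      tab <- tab[keep, , drop = FALSE]
      wlist <- wlist[keep]
    }
  }
  structure(list(summaries = tab, weights = wlist,
                 se_order = se_order, K = nrow(tab)),
            class = "sss_summaries")
}

#' @export
print.sss_summaries <- function(x, ...) {
  cat(sprintf("<sss_summaries> K = %d strata (%s-order errors)\n",
              x$K, x$se_order))
  print(utils::head(x$summaries, 10L))
  if (x$K > 10L) cat("...\n")
  invisible(x)
}

#' Cochran's Q test of effect linearity across strata
#'
#' Under a linear (constant-intensity) effect, all stratum Wald ratios share
#' the same estimand; heterogeneity beyond sampling noise indicates a
#' nonlinear effect (or effect modification). Computes the inverse-variance-
#' weighted pooled estimate and Q = sum_k (beta_k - pooled)^2 / se_k^2,
#' referred to a chi-squared distribution with K - 1 degrees of freedom.
#'
#' @param summaries an `sss_summaries` object (or its `summaries` data frame).
#' @return list with `Q`, `df`, `p_value` and `beta_pooled`.
#' @export
linearity_q_test <- function(summaries) {
  tab <- if (inherits(summaries, "sss_summaries")) summaries$summaries else summaries
  stopifnot(all(c("beta_hat", "se_beta") %in% names(tab)))
  tab <- tab[is.finite(tab$beta_hat) & is.finite(tab$se_beta), , drop = FALSE]
  if (nrow(tab) < 2L) stop("need at least 2 strata with finite estimates")
  if (any(tab$se_beta == 0)) stop("zero standard error in a stratum")
  w <- 1 / tab$se_beta^2
  pooled <- sum(w * tab$beta_hat) / sum(w)
  Q <- sum(w * (tab$beta_hat - pooled)^2)
  df <- nrow(tab) - 1L
  list(Q = Q, df = df, p_value = stats::pchisq(Q, df, lower.tail = FALSE),
       beta_pooled = pooled)
}

#' Write per-stratum summaries and weight functions to CSV
#'
#' @param summaries an `sss_summaries` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written: `strata_summary.csv` plus one
#'   two-column (breakpoint, height) CSV per stratum weight function.
#' @export
write_summaries <- function(summaries, dir) {
  stopifnot(inherits(summaries, "sss_summaries"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  main <- file.path(dir, "strata_summary.csv")
  utils::write.csv(summaries$summaries[, c("k", "n_k", "alpha_hat",
                                           "theta_hat", "beta_hat",
                                           "se_beta", "xbar")],
                   main, row.names = FALSE)
  paths <- main
  for (i in seq_len(summaries$K)) {
    w <- summaries$weights[[i]]
    p <- file.path(dir, sprintf("weight_stratum_%03d.csv",
                                summaries$summaries$k[i]))
    utils::write.csv(data.frame(breakpoint = w$breaks,
                                height = c(w$heights, NA)),
                     p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
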