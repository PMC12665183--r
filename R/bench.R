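#' Theoretical exposure quantiles for the simulation scenarios
#'
#' Computed from the closed-form exposure law each scenario implies, not from
#' sample quantiles. With a binary instrument the exposure is an equal
#' mixture of two normals shifted by +-0.075 (or +-0.15 on the log scale for
#' the lognormal designs); with a normal instrument it is a single normal
#' (lognormal after exponentiation). Mixture quantiles are found by root
#' search on the mixture CDF.
#'
#' @param part `"I"`, `"II"` or `"III"`.
#' @param scenario scenario number (Parts I and III).
#' @param probs quantile probabilities.
#' @return numeric vector of exposure quantiles.
#' @export
theoretical_quantiles <- function(part, scenario = 1L,
                                  probs = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  sd_rest <- sqrt(2)            # sd of U + eps_X
  mix_q <- function(p, delta, s) {
    vapply(p, function(pp) {
      stats::uniroot(function(q)
        0.5 * stats::pnorm(q, -delta, s) + 0.5 * stats::pnorm(q, delta, s) - pp,
        interval = c(-20 * s, 20 * s), tol = 1e-10)$root
    }, numeric(1))
  }
  if (part %in% c("I", "II")) {
    binary <- part == "II" || scenario %in% c(1L, 2L)
    if (binary) return(mix_q(probs, 0.075, sd_rest))
    return(stats::qnorm(probs, 0, sqrt(0.15^2 + 2)))
  }
  switch(as.character(scenario),
         "1" = mix_q(probs, 0.075, sd_rest),
         "2" = stats::qnorm(probs, 0, sqrt(0.15^2 + 2)),
         "3" = exp(mix_q(probs, 0.15, sd_rest)),
         "4" = exp(stats::qnorm(probs, 0, sqrt(0.3^2 + 2))),
         stop("unknown scenario"))
}

# deterministic per-replicate seed pool for a benchmark configuration
replicate_seeds <- function(master_seed, n_reps, config_index = 1L) {
  set.seed(master_seed + 7919L * (config_index - 1L))
  sample.int(2147483646L, n_reps)
}

# run one estimator on one dataset; returns predictions at the evaluation
# points (effect h for Parts I/III, intensity h' for Part II) or NULL on a
# fit failure.
run_method <- function(method, ds, eval_x, K, L = 10L) {
  data <- ds$data
  part <- ds$spec$part
  if (method == "M1") {
    f <- fit_control_function(data)
    if (!f$ok) return(NULL)
    return(f$h(eval_x))
  }
  if (method == "M2") {
    f <- fit_iv_regression(data)
    if (!f$ok) return(NULL)
    return(f$h(eval_x))
  }
  strata <- doubly_ranked_stratify(data, K)
  summ <- suppressWarnings(stratum_summaries(strata))
  if (method == "M3") {
    fit <- fit_sos(summ, basis_spec("polynomial", degree = 1L))
    return(effect_curve(fit, eval_x)$h)
  }
  if (method %in% c("SoS", "SoF")) {
    basis <- if (identical(ds$spec$effect_case, "jump"))
      basis_spec("changepoint", candidates = 0) else
      basis_spec("polynomial", degree = 1L)
    fit <- if (method == "SoS") fit_sos(summ, basis) else fit_sof(summ, basis)
    return(effect_curve(fit, eval_x)$h_prime)
  }
  if (method == "M5") {
    style <- if (part == "III" && ds$spec$scenario %in% c(3L, 4L))
      "left95" else "middle90"
    cand <- changepoint_candidates(data$X, style)
    des <- suppressMessages(build_changepoint_design(summ, cand))
    fit <- suppressWarnings(susie_changepoint(des, L = L))
    return(drop(cp_contrast_grid(eval_x, cand) %*% fit$b_post))
  }
  stop("unknown method: ", method)
}

#' Replicate-loop simulation benchmark
#'
#' For each replicate: generates a dataset, runs each estimator, evaluates
#' the estimated effect function (Parts I and III) or effect intensity
#' (Part II) at the theoretical exposure quantiles, and averages squared
#' errors against the truth. Fit failures (singular designs) are excluded
#' from the affected cells with a reported count. The per-cell Monte-Carlo
#' standard error of the MSE estimate is reported as `mc_se`.
#'
#' Default designs follow the study conditions: Part I n = 5000 with K = 100
#' strata; Parts II and III n = 50000 with K in \{10, 50, 100\} and K = 100
#' respectively.
#'
#' @param part `"I"`, `"II"` or `"III"`.
#' @param scenarios scenario subset (Parts I and III).
#' @param methods subset of `"M1"`, `"M2"`, `"M3"`, `"M5"`, `"SoS"`, `"SoF"`.
#' @param n_reps number of replicates.
#' @param n per-replicate sample size (default 5000 for Part I, 50000
#'   otherwise).
#' @param K strata count (default 100; use 10/50/100 for Part II).
#' @param effect_case Part II `"linear_quadratic"`/`"jump"` or Part III 1-4.
#' @param eval_probs evaluation quantile probabilities.
#' @param master_seed seed controlling the whole replicate loop.
#' @param L maximum SuSiE effects for `"M5"`.
#' @return data frame with one row per (scenario, case, method, quantile):
#'   columns `part`, `scenario`, `effect_case`, `method`, `prob`, `eval_x`,
#'   `mse`, `mc_se`, `n_ok`, `n_fail`.
#' @export
run_benchmark <- function(part, scenarios = 1L, methods = c("M1", "M2", "M3", "M5"),
                          n_reps = 200L, n = NULL, K = 100L,
                          effect_case = NULL,
                          eval_probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                          master_seed = 1L, L = 10L) {
  if (is.null(n)) n <- if (part == "I") 5000L else 50000L
  if (part == "II") {
    scenarios <- 1L
    if (is.null(effect_case)) stop("Part II requires an effect_case")
  }
  cases <- if (is.null(effect_case)) list(NULL) else as.list(effect_case)
  out <- list()
  cfg <- 0L
  for (sc in scenarios) for (ec in cases) {
    cfg <- cfg + 1L
    seeds <- replicate_seeds(master_seed, n_reps, cfg)
    eval_x <- theoretical_quantiles(part, sc, eval_probs)
    errs <- array(NA_real_, c(n_reps, length(methods), length(eval_x)))
    for (r in seq_len(n_reps)) {
      spec <- scenario_spec(part, sc, effect_case = ec, n = n, seed = seeds[r])
      ds <- generate_iv_data(spec)
      truth <- if (part == "II") ds$true_effect$h_prime(eval_x)
               else ds$true_effect$h(eval_x)
      for (mi in seq_along(methods)) {
        pred <- tryCatch(run_method(methods[mi], ds, eval_x, K, L),
                         error = function(e) NULL)
        if (!is.null(pred)) errs[r, mi, ] <- (pred - truth)^2
      }
    }
    for (mi in seq_along(methods)) for (qi in seq_along(eval_x)) {
      e <- errs[, mi, qi]
      ok <- is.finite(e)
      out[[length(out) + 1L]] <- data.frame(
        part = part, scenario = sc,
        effect_case = if (is.null(ec)) NA else as.character(ec),
        method = methods[mi], prob = eval_probs[qi], eval_x = eval_x[qi],
        mse = mean(e[ok]), mc_se = stats::sd(e[ok]) / sqrt(sum(ok)),
        n_ok = sum(ok), n_fail = sum(!ok))
    }
  }
  do.call(rbind, out)
}

#' Average instrument strength (R-squared) under a simulation design
#'
#' Regresses X on Z in repeated simulated samples and averages the
#' coefficient of determination.
#'
#' @param part,scenario simulation design.
#' @param n sample size per replicate.
#' @param n_reps replicates.
#' @param master_seed seed.
#' @return list with `r_squared` (the average) and `per_rep`.
#' @export
instrument_strength <- function(part = "III", scenario = 1L, n = 50000L,
                                n_reps = 50L, master_seed = 1L) {
  seeds <- replicate_seeds(master_seed, n_reps)
  r2 <- vapply(seq_len(n_reps), function(r) {
    ec <- if (part == "III") 1L else if (part == "II") "linear_quadratic" else NULL
    ds <- generate_iv_data(scenario_spec(part, scenario, effect_case = ec,
                                         n = n, seed = seeds[r]))
    summary(stats::lm(X ~ Z, data = ds$data))$r.squared
  }, numeric(1))
  list(r_squared = mean(r2), per_rep = r2)
}

#' Change-point recovery study
#'
#' Runs the full stratification + change-point SuSiE pipeline on replicated
#' one-change-point datasets (Part III effect case 2) and records, per
#' replicate, the effective number of detected effects and the posterior
#' mode and mean of the first detected change-point.
#'
#' @param scenario Part III scenario 1-4.
#' @param n_reps replicates.
#' @param n per-replicate sample size.
#' @param K strata.
#' @param L maximum SuSiE effects.
#' @param master_seed seed.
#' @return data frame with columns `rep`, `L_star`, `mode`, `mean`,
#'   `intercept_pip`.
#' @export
changepoint_recovery <- function(scenario = 1L, n_reps = 100L, n = 50000L,
                                 K = 100L, L = 10L, master_seed = 1L) {
  seeds <- replicate_seeds(master_seed, n_reps, config_index = scenario)
  style <- if (scenario %in% c(3L, 4L)) "left95" else "middle90"
  rows <- lapply(seq_len(n_reps), function(r) {
    ds <- generate_iv_data(scenario_spec("III", scenario, effect_case = 2L,
                                         n = n, seed = seeds[r]))
    strata <- doubly_ranked_stratify(ds$data, K)
    summ <- suppressWarnings(stratum_summaries(strata))
    cand <- changepoint_candidates(ds$data$X, style)
    des <- suppressMessages(build_changepoint_design(summ, cand))
    fit <- suppressWarnings(susie_changepoint(des, L = L))
    cs <- changepoint_summary(fit)
    first <- if (nrow(cs)) cs[1L, ] else
      data.frame(mode = NA_real_, mean = NA_real_, intercept_pip = NA_real_)
    data.frame(rep = r, L_star = fit$L_star, mode = first$mode,
               mean = first$mean, intercept_pip = first$intercept_pip)
  })
  do.call(rbind, rows)
}
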