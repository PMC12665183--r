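#' Read an instrument-exposure-outcome table from CSV
#'
#' @param path CSV file with at least the instrument, exposure and outcome
#'   columns.
#' @param z,x,y column names (defaults `Z`, `X`, `Y`).
#' @return data frame with standardized column names `Z`, `X`, `Y` (other
#'   columns preserved), rows with missing values dropped with a message.
#' @export
read_iv_csv <- function(path, z = "Z", x = "X", y = "Y") {
  dat <- utils::read.csv(path)
  miss <- setdiff(c(z, x, y), names(dat))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  names(dat)[match(c(z, x, y), names(dat))] <- c("Z", "X", "Y")
  as_iv_data(dat)
}

#' Complete stratified nonlinear IV analysis
#'
#' Runs the staged workflow: stratification, per-stratum IV summaries, the
#' Cochran's-Q linearity test, then the selected effect model -- a
#' scalar-on-function or scalar-on-scalar basis regression, or the
#' change-point SuSiE analysis (the default) with credible sets and a
#' posterior effect curve. When an output directory is given, all results
#' are written as CSV/JSON together with a `manifest.json` recording the
#' configuration, package version and seed, sufficient to reproduce the
#' outputs exactly.
#'
#' @param data data frame with columns `Z`, `X`, `Y`, or a CSV path.
#' @param method stratification method, `"doubly_ranked"` or `"residual"`.
#' @param K number of strata.
#' @param se_order Wald-ratio error order, `"first"` or `"second"`.
#' @param model `"changepoint"` (default), `"sof"` or `"sos"`.
#' @param basis a [basis_spec()] for the sof/sos models (default quadratic
#'   polynomial).
#' @param candidates change-point candidates for the changepoint model
#'   (default: `candidate_style` quantile grid of the exposure).
#' @param candidate_style `"middle90"` or `"left95"` (see
#'   [changepoint_candidates()]).
#' @param L maximum SuSiE effects.
#' @param lambda penalty for sof/sos (`0`, a value, or `"gcv"`).
#' @param draws posterior draws for the credible band.
#' @param grid_length effect-curve grid resolution.
#' @param seed seed for the posterior sampling.
#' @param out_dir optional output directory.
#' @param drop_weak drop weak strata (default retain with a warning).
#' @return an object of class `sss_pipeline`: list with `strata`,
#'   `summaries`, `q_test`, `fit`, `curve`, `changepoints` (changepoint
#'   model only) and `manifest`.
#' @export
run_pipeline <- function(data, method = c("doubly_ranked", "residual"),
                         K = 10L, se_order = c("first", "second"),
                         model = c("changepoint", "sof", "sos"),
                         basis = NULL, candidates = NULL,
                         candidate_style = c("middle90", "left95"),
                         L = 10L, lambda = 0, draws = 10000L,
                         grid_length = 100L, seed = 1L, out_dir = NULL,
                         drop_weak = FALSE) {
  method <- match.arg(method)
  model <- match.arg(model)
  se_order <- match.arg(se_order)
  candidate_style <- match.arg(candidate_style)
  if (is.character(data) && length(data) == 1L) data <- read_iv_csv(data)

  strata <- if (method == "doubly_ranked") doubly_ranked_stratify(data, K)
            else residual_stratify(data, K)
  summ <- stratum_summaries(strata, se_order = se_order,
                            drop_weak = drop_weak)
  qt <- linearity_q_test(summ)
  grid <- seq(min(data$X), max(data$X), length.out = grid_length)

  cps <- NULL
  if (model == "changepoint") {
    if (is.null(candidates))
      candidates <- changepoint_candidates(strata_data(strata)$X,
                                           candidate_style)
    des <- build_changepoint_design(summ, candidates)
    fit <- susie_changepoint(des, L = L)
    set.seed(seed)
    curve <- posterior_effect_curve(fit, grid, n_draws = draws)
    cps <- changepoint_summary(fit)
    if (fit$L_star >= max(3L, L - 1L))
      message("many change-points detected (L* = ", fit$L_star,
              "): the intensity may be smooth; consider a parametric basis fit")
  } else {
    if (is.null(basis)) basis <- basis_spec("polynomial", degree = 2L)
    fit <- if (model == "sof") fit_sof(summ, basis, lambda = lambda)
           else fit_sos(summ, basis, lambda = lambda)
    curve <- effect_curve(fit, grid)
  }

  manifest <- list(package = "sssiv",
                   version = as.character(utils::packageVersion("sssiv")),
                   config = list(method = method, K = K, se_order = se_order,
                                 model = model, L = L, lambda = lambda,
                                 draws = draws, grid_length = grid_length,
                                 seed = seed,
                                 candidate_style = candidate_style),
                   n = nrow(strata$data), dropped = strata$dropped,
                   q_test = qt[c("Q", "df", "p_value", "beta_pooled")])
  res <- structure(list(strata = strata, summaries = summ, q_test = qt,
                        fit = fit, curve = curve, changepoints = cps,
                        manifest = manifest),
                   class = "sss_pipeline")
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

#' @export
print.sss_pipeline <- function(x, ...) {
  cat("<sss_pipeline>\n")
  cat(sprintf("  strata: %s, K = %d\n", x$strata$method, x$summaries$K))
  cat(sprintf("  linearity Q = %.3f (df %d), p = %.3g\n",
              x$q_test$Q, x$q_test$df, x$q_test$p_value))
  if (inherits(x$fit, "sss_susie"))
    cat(sprintf("  change-point model: L* = %d detected effect(s)\n",
                x$fit$L_star))
  else
    cat(sprintf("  %s fit, %d basis functions\n", toupper(x$fit$model),
                length(x$fit$b_hat)))
  invisible(x)
}

#' Write a pipeline result bundle
#'
#' Emits `strata_summary.csv`, per-stratum weight-function CSVs,
#' `effect_curve.csv`, and -- for the change-point model -- `pip.csv` and
#' `credible_sets.json`, plus `manifest.json`.
#'
#' @param res an `sss_pipeline` result.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the output directory.
#' @export
write_pipeline <- function(res, out_dir) {
  stopifnot(inherits(res, "sss_pipeline"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_summaries(res$summaries, out_dir)
  utils::write.csv(as.data.frame(res$curve),
                   file.path(out_dir, "effect_curve.csv"), row.names = FALSE)
  if (inherits(res$fit, "sss_susie")) {
    fit <- res$fit
    pip <- as.data.frame(fit$pip[fit$active, , drop = FALSE])
    names(pip) <- c("intercept", paste0("t_", seq_along(fit$candidates)))
    utils::write.csv(pip, file.path(out_dir, "pip.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(candidates = fit$candidates,
           credible_sets = lapply(which(fit$active),
                                  function(l) fit$credible_sets[[l]]),
           summary = res$changepoints),
      file.path(out_dir, "credible_sets.json"),
      auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
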