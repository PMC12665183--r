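#' Simulation scenario specification
#'
#' Describes one dataset from the weak-instrument simulation designs used
#' throughout the package. Three study parts are supported:
#'
#' * **Part I** (`part = "I"`): linear effect `h(x) = x`, exposure
#'   `X = 0.15 Z + U + eps_X`. Scenarios 1-2 use a binary instrument
#'   `Z ~ Bernoulli(0.5) - 0.5`, scenarios 3-4 a standard normal instrument;
#'   scenarios 1 and 3 have simple additive confounding
#'   `Y = X + U + eps_Y`, scenarios 2 and 4 the complex confounding
#'   `Y = X + |U| + eps_X^2 + 2|U||eps_X| + eps_Y`.
#' * **Part II** (`part = "II"`): binary instrument, same exposure model,
#'   `Y = h(X) + U + eps_Y` with `effect_case` `"linear_quadratic"`
#'   (`h(x) = x + 0.5 x^2`, intensity `1 + 2x`) or `"jump"`
#'   (`h(x) = I(x >= 0)`, intensity `I(x > 0)`).
#' * **Part III** (`part = "III"`): four instrument-exposure models
#'   (scenario 1: binary Z, `X = 0.15 Z + U + eps_X`; 2: normal Z, same X;
#'   3: binary Z, `X = exp(0.3 Z + U + eps_X)`; 4: normal Z, same lognormal
#'   X), crossed with four effect cases (`effect_case` 1-4), all anchored at
#'   `h(0) = 0`: linear, one change-point, two change-points, and a smooth
#'   quadratic intensity. `Y = h(X) + U + eps_Y`.
#'
#' All noise terms are independent standard normal. The instrument effects
#' (0.15 additive, 0.3 on the log scale) give an instrument R-squared of
#' roughly 0.003 (binary Z) or 0.01 (normal Z), typical of genetic scores in
#' Mendelian randomization.
#'
#' @param part `"I"`, `"II"` or `"III"`.
#' @param scenario integer 1-4 (Parts I and III; ignored for Part II).
#' @param effect_case integer 1-4 (Part III) or `"linear_quadratic"`/`"jump"`
#'   (Part II).
#' @param n sample size (> 0).
#' @param seed integer seed; identical (spec, seed) pairs reproduce identical
#'   datasets bit for bit.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(part = c("I", "II", "III"), scenario = 1L,
                          effect_case = NULL, n, seed = 1L) {
  part <- match.arg(part)
  n <- as.integer(n)
  if (is.na(n) || n <= 0L) stop("n must be a positive integer")
  if (part == "I") {
    if (!scenario %in% 1:4)
      stop("Part I admits scenario 1-4 (binary/normal instrument x simple/complex confounding)")
    effect_case <- NULL
  } else if (part == "II") {
    if (is.null(effect_case) ||
        !effect_case %in% c("linear_quadratic", "jump"))
      stop("Part II admits effect_case 'linear_quadratic' or 'jump'")
    scenario <- 1L
  } else {
    if (!scenario %in% 1:4)
      stop("Part III admits scenario 1-4 (binary/normal instrument x normal/lognormal exposure)")
    if (is.null(effect_case) || !effect_case %in% 1:4)
      stop("Part III admits effect_case 1-4 (linear / one change-point / two change-points / quadratic intensity)")
  }
  structure(list(part = part, scenario = as.integer(scenario),
                 effect_case = effect_case, n = n, seed = as.integer(seed)),
            class = "scenario_spec")
}

# true effect function, intensity and change-points for a spec
true_effect_for <- function(spec) {
  if (spec$part == "I")
    return(list(h = function(x) x, h_prime = function(x) rep(1, length(x)),
                changepoints = numeric(0)))
  if (spec$part == "II") {
    if (spec$effect_case == "linear_quadratic")
      return(list(h = function(x) x + 0.5 * x^2,
                  h_prime = function(x) 1 + 2 * x,
                  changepoints = numeric(0)))
    # jump intensity: h'(x) = I{x > 0}, i.e. the hinge effect h(x) = (x)_+
    return(list(h = function(x) pmax(x, 0),
                h_prime = function(x) as.numeric(x > 0),
                changepoints = 0))
  }
  lognormal <- spec$scenario %in% c(3L, 4L)
  pos <- function(v) pmax(v, 0)
  if (!lognormal) {
    switch(spec$effect_case,
      `1` = list(h = function(x) x,
                 h_prime = function(x) rep(1, length(x)),
                 changepoints = numeric(0)),
      `2` = list(h = function(x) pos(x),
                 h_prime = function(x) as.numeric(x > 0),
                 changepoints = 0),
      `3` = list(h = function(x) 0.5 * x + 0.5 * pos(x + 0.5) - 0.25 +
                                 0.5 * pos(x - 0.5),
                 h_prime = function(x) 0.5 + 0.5 * (x > -0.5) + 0.5 * (x > 0.5),
                 changepoints = c(-0.5, 0.5)),
      `4` = list(h = function(x) -x + 0.5 * x^2,
                 h_prime = function(x) -1 + x,
                 changepoints = numeric(0)))
  } else {
    switch(spec$effect_case,
      `1` = list(h = function(x) x,
                 h_prime = function(x) rep(1, length(x)),
                 changepoints = numeric(0)),
      `2` = list(h = function(x) pos(x - 2.5),
                 h_prime = function(x) as.numeric(x > 2.5),
                 changepoints = 2.5),
      `3` = list(h = function(x) 0.5 * x + 0.5 * pos(x - 0.5) + 0.5 * pos(x - 2.5),
                 h_prime = function(x) 0.5 + 0.5 * (x > 0.5) + 0.5 * (x > 2.5),
                 changepoints = c(0.5, 2.5)),
      `4` = list(h = function(x) -2 * x + 0.5 * x^2,
                 h_prime = function(x) -2 + x,
                 changepoints = numeric(0)))
  }
}

#' Generate a simulation dataset
#'
#' Draws `spec$n` observations from the structural equations of the given
#' scenario (see [scenario_spec()]). The confounder column `U` is retained in
#' the returned data for diagnostics (e.g. the collider-bias contrast between
#' exposure- and counterfactual-exposure-based stratification); it is never
#' used by the estimation code.
#'
#' @param spec a [scenario_spec()].
#' @return an object of class `sss_dataset`: list with `data`
#'   (data frame `id, Z, X, Y, U`), `true_effect` (list of functions `h`,
#'   `h_prime`), `true_changepoints`, and `spec`.
#' @export
generate_iv_data <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  n <- spec$n
  # Part I: scenarios 1-2 binary instrument; Part III: odd scenarios binary.
  binary_z <- switch(spec$part,
                     I = spec$scenario %in% c(1L, 2L),
                     II = TRUE,
                     III = spec$scenario %in% c(1L, 3L))
  Z <- if (binary_z) stats::rbinom(n, 1L, 0.5) - 0.5 else stats::rnorm(n)
  U <- stats::rnorm(n)
  eX <- stats::rnorm(n)
  eY <- stats::rnorm(n)
  lognormal <- spec$part == "III" && spec$scenario %in% c(3L, 4L)
  X <- if (lognormal) exp(0.3 * Z + U + eX) else 0.15 * Z + U + eX
  te <- true_effect_for(spec)
  Y <- if (spec$part == "I" && spec$scenario %in% c(2L, 4L)) {
    X + abs(U) + eX^2 + 2 * abs(U) * abs(eX) + eY
  } else {
    te$h(X) + U + eY
  }
  structure(list(data = data.frame(id = seq_len(n), Z = Z, X = X, Y = Y, U = U),
                 true_effect = te[c("h", "h_prime")],
                 true_changepoints = te$changepoints,
                 spec = spec),
            class = "sss_dataset")
}

#' @export
print.sss_dataset <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<sss_dataset> Part %s scenario %d%s, n = %d, seed = %d\n",
              s$part, s$scenario,
              if (is.null(s$effect_case)) "" else paste0(" case ", s$effect_case),
              s$n, s$seed))
  invisible(x)
}

#' Write a generated dataset as CSV with a JSON sidecar
#'
#' The CSV has header `id,Z,X,Y`; the sidecar `<path>.json` records the
#' scenario specification, seed and true change-points.
#'
#' @param ds an `sss_dataset`.
#' @param path output CSV path.
#' @return invisibly, the two paths written.
#' @export
write_iv_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "sss_dataset"))
  utils::write.csv(ds$data[, c("id", "Z", "X", "Y")], path, row.names = FALSE)
  side <- paste0(path, ".json")
  jsonlite::write_json(list(spec = unclass(ds$spec),
                            true_changepoints = ds$true_changepoints),
                       side, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(path, side))
}

#' Oracle control-function estimator (quadratic effect)
#'
#' Two-step residual-inclusion fit assuming the true effect is a quadratic
#' polynomial: the first stage regresses X on Z to obtain the residual r; the
#' second stage fits Y on \{X, X^2, r\} by least squares. The implied effect
#' curve is `h(x) = b1 x + b2 x^2` (anchored at h(0) = 0).
#'
#' @param data data frame with columns `Z`, `X`, `Y`.
#' @return list with `ok` (FALSE on a singular second-stage design -- a fit
#'   failure, not an error), `coef` `(b1, b2)` and `h`, the estimated effect
#'   function.
#' @export
fit_control_function <- function(data) {
  stopifnot(all(c("Z", "X", "Y") %in% names(data)))
  if (length(unique(data$X)) < 3L) stop("need at least 3 distinct X values")
  r <- stats::residuals(stats::lm(X ~ Z, data = data))
  fit <- stats::lm(data$Y ~ data$X + I(data$X^2) + r)
  cf <- stats::coef(fit)
  if (anyNA(cf)) return(list(ok = FALSE, coef = c(NA_real_, NA_real_)))
  b <- unname(cf[2:3])
  list(ok = TRUE, coef = b, h = function(x) b[1] * x + b[2] * x^2)
}

#' Oracle IV-regression estimator (quadratic effect, exact identification)
#'
#' Dichotomizes the instrument (its two levels when binary; split at the
#' empirical median when continuous) and solves the 2x2 exact-identification
#' system
#' `E(Y | z*) = b1 E(X | z*) + b2 E(X^2 | z*)`, `z* = 0, 1`,
#' for the quadratic effect coefficients.
#'
#' @param data data frame with columns `Z`, `X`, `Y`.
#' @return list with `ok` (FALSE on a singular moment matrix), `coef`
#'   `(b1, b2)` and `h`.
#' @export
fit_iv_regression <- function(data) {
  stopifnot(all(c("Z", "X", "Y") %in% names(data)))
  zu <- sort(unique(data$Z))
  grp <- if (length(zu) == 2L) as.integer(data$Z == zu[2L])
         else as.integer(data$Z > stats::median(data$Z))
  if (length(unique(grp)) < 2L) return(list(ok = FALSE, coef = c(NA_real_, NA_real_)))
  m <- function(v, g) mean(v[grp == g])
  M <- rbind(c(m(data$X, 0L), m(data$X^2, 0L)),
             c(m(data$X, 1L), m(data$X^2, 1L)))
  rhs <- c(m(data$Y, 0L), m(data$Y, 1L))
  det_m <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  if (!is.finite(det_m) || abs(det_m) < 1e-12 * max(abs(M)))
    return(list(ok = FALSE, coef = c(NA_real_, NA_real_)))
  b <- unname(solve(M, rhs))
  list(ok = TRUE, coef = b, h = function(x) b[1] * x + b[2] * x^2)
}
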