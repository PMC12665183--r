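#' Basis specification for the effect intensity h'(x)
#'
#' The effect intensity is modelled as `h'(x) = sum_l b_l phi_l(x)`. Three
#' families are supported:
#'
#' * `"polynomial"`: `phi = (1, x, ..., x^degree)`, L = degree + 1.
#' * `"changepoint"`: an intercept (constant 1) plus indicator functions
#'   `I(x >= t_p)` at the supplied `candidates`, L = P + 1.
#' * `"bspline"`: B-splines of the given `degree` with interior `knots` on
#'   `range` (boundary knots at the range endpoints).
#'
#' @param family basis family.
#' @param degree polynomial/spline degree (polynomial default 1, bspline
#'   default 3).
#' @param knots interior knots (bspline).
#' @param candidates change-point thresholds t_p (changepoint family), sorted.
#' @param range exposure range `c(lo, hi)` over which spline bases and
#'   penalties are defined.
#' @return an object of class `basis_spec` with element `L`, the number of
#'   basis functions.
#' @export
basis_spec <- function(family = c("polynomial", "changepoint", "bspline"),
                       degree = NULL, knots = NULL, candidates = NULL,
                       range = NULL) {
  family <- match.arg(family)
  if (family == "polynomial") {
    if (is.null(degree)) degree <- 1L
    L <- degree + 1L
  } else if (family == "changepoint") {
    if (is.null(candidates) || length(candidates) < 1L)
      stop("changepoint basis needs at least one candidate threshold")
    if (is.unsorted(candidates, strictly = TRUE))
      stop("candidates must be strictly increasing")
    L <- length(candidates) + 1L
  } else {
    if (is.null(degree)) degree <- 3L
    if (is.null(range)) stop("bspline basis requires an exposure range")
    knots <- sort(knots)
    L <- length(knots) + degree + 1L
  }
  structure(list(family = family, degree = degree, knots = knots,
                 candidates = candidates, range = range, L = as.integer(L)),
            class = "basis_spec")
}

bspline_all_knots <- function(basis) {
  c(rep(basis$range[1L], basis$degree + 1L), basis$knots,
    rep(basis$range[2L], basis$degree + 1L))
}

#' Evaluate the basis functions
#'
#' @param basis a [basis_spec()].
#' @param x evaluation points.
#' @param deriv derivative order (0 = the functions themselves; bspline and
#'   polynomial only).
#' @return `length(x)` x `L` matrix.
#' @export
basis_eval <- function(basis, x, deriv = 0L) {
  switch(basis$family,
    polynomial = {
      sapply(0:basis$degree, function(j) {
        if (deriv == 0L) x^j
        else if (j < deriv) rep(0, length(x))
        else prod((j - deriv + 1L):j) * x^(j - deriv)
      }) |> matrix(nrow = length(x))
    },
    changepoint = {
      if (deriv > 0L) stop("indicator bases are not differentiable")
      # open-set convention: the intensity I{x > t} is 0 at the threshold
      # itself, matching the hinge effect (x - t)_+ whose left derivative at
      # t is 0; the exact inner products <phi, W> are unaffected.
      cbind(1, outer(x, basis$candidates, ">"))
    },
    bspline = {
      ak <- bspline_all_knots(basis)
      xc <- pmin(pmax(x, basis$range[1L]), basis$range[2L])
      splines::splineDesign(ak, xc, ord = basis$degree + 1L,
                            derivs = rep(deriv, length(x)))
    })
}

#' Exact antiderivative of the basis, anchored at 0
#'
#' Returns the matrix of `int_0^x phi_l(s) ds`, used to reconstruct the
#' effect curve h(x) with h(0) = 0 exactly. Indicator antiderivatives are the
#' hinge contrasts `(x - t)_+ - (0 - t)_+`; polynomial ones are closed form;
#' B-spline ones use piecewise Gauss-Legendre quadrature exact for the spline
#' degree.
#'
#' @param basis a [basis_spec()].
#' @param x evaluation points.
#' @return `length(x)` x `L` matrix.
#' @export
basis_antideriv <- function(basis, x) {
  switch(basis$family,
    polynomial = {
      sapply(0:basis$degree, function(j) x^(j + 1) / (j + 1)) |>
        matrix(nrow = length(x))
    },
    changepoint = {
      hinge <- function(t) pmax(x - t, 0) - max(-t, 0)
      cbind(x, sapply(basis$candidates, hinge) |> matrix(nrow = length(x)))
    },
    bspline = {
      pieces <- sort(unique(c(0, basis$range, basis$knots, x)))
      gl <- gauss_legendre(ceiling((basis$degree + 1L) / 2))
      lo <- pieces[-length(pieces)]; hi <- pieces[-1L]
      mid <- (lo + hi) / 2; half <- (hi - lo) / 2
      seg <- matrix(0, length(lo), basis$L)
      for (q in seq_along(gl$x)) {
        seg <- seg + gl$w[q] * half * basis_eval(basis, mid + gl$x[q] * half)
      }
      cum <- apply(seg, 2L, cumsum)                  # integral from pieces[1]
      at <- rbind(0, cum)[match(x, pieces), , drop = FALSE]
      at0 <- rbind(0, cum)[match(0, pieces), ]
      sweep(at, 2L, at0)
    })
}

#' Roughness penalty matrix
#'
#' `R[i, j] = int (D^m phi_i)(x) (D^m phi_j)(x) dx` over the basis range.
#' Indicator bases are piecewise constant, so their derivative penalty is not
#' defined; the changepoint family returns a zero matrix and should be fitted
#' unpenalised (lambda = 0).
#'
#' @param basis a [basis_spec()].
#' @param m derivative order (default 2).
#' @param range integration range (defaults to `basis$range`, required for
#'   polynomials if the spec has none).
#' @return symmetric positive semidefinite `L x L` matrix.
#' @export
basis_penalty <- function(basis, m = 2L, range = basis$range) {
  L <- basis$L
  if (basis$family == "changepoint") return(matrix(0, L, L))
  if (is.null(range)) stop("a range is required to integrate the penalty")
  if (basis$family == "polynomial") {
    R <- matrix(0, L, L)
    if (m > basis$degree) return(R)   # all m-th derivatives vanish
    for (i in m:basis$degree) for (j in m:basis$degree) {
      ci <- prod((i - m + 1L):i); cj <- prod((j - m + 1L):j)
      pw <- i + j - 2L * m + 1L
      R[i + 1L, j + 1L] <- ci * cj * (range[2L]^pw - range[1L]^pw) / pw
    }
    return(R)
  }
  # bspline: D^m phi piecewise polynomial of degree (degree - m)
  pieces <- sort(unique(c(range, basis$knots)))
  deg <- max(basis$degree - m, 0L)
  gl <- gauss_legendre(max(1L, ceiling((2L * deg + 1L) / 2)))
  R <- matrix(0, L, L)
  lo <- pieces[-length(pieces)]; hi <- pieces[-1L]
  mid <- (lo + hi) / 2; half <- (hi - lo) / 2
  for (q in seq_along(gl$x)) {
    B <- basis_eval(basis, mid + gl$x[q] * half, deriv = m)
    R <- R + gl$w[q] * crossprod(B * sqrt(half))
  }
  (R + t(R)) / 2
}

#' Scalar-on-function design matrix
#'
#' Fills the K x L design with exact inner products `<phi_l, W_k>` of each
#' basis function against each stratum's step-function weight: polynomial
#' entries from exact moments, indicator entries from exact tail masses, and
#' B-spline entries by Gauss-Legendre quadrature exact for the spline degree
#' on every weight step (subdivided at the knots).
#'
#' @param summaries an `sss_summaries` object.
#' @param basis a [basis_spec()].
#' @return `K x L` numeric matrix.
#' @export
build_sof_design <- function(summaries, basis) {
  stopifnot(inherits(summaries, "sss_summaries"))
  K <- summaries$K
  X <- matrix(NA_real_, K, basis$L)
  for (k in seq_len(K)) {
    w <- summaries$weights[[k]]
    if (basis$family == "bspline") {
      rng <- range(w$breaks)
      if (rng[1L] < basis$range[1L] - 1e-10 || rng[2L] > basis$range[2L] + 1e-10)
        stop("basis support does not cover the weight support of stratum ",
             summaries$summaries$k[k])
    }
    X[k, ] <- switch(basis$family,
      polynomial = vapply(0:basis$degree, function(p) wf_moment(w, p),
                          numeric(1)),
      changepoint = c(wf_integral(w), wf_tail(w, basis$candidates)),
      bspline = vapply(seq_len(basis$L), function(l) {
        wf_inner_fun(w, function(s) basis_eval(basis, s)[, l],
                     cuts = basis$knots,
                     nodes = max(1L, ceiling((basis$degree + 1L) / 2)))
      }, numeric(1)))
  }
  X
}

fit_weighted_basis <- function(design, beta_hat, se_beta, basis,
                               lambda = 0, m = 2L, R = NULL, model = "sof") {
  K <- nrow(design)
  if (is.null(R)) {
    R <- if (lambda > 0) basis_penalty(basis, m) else
      matrix(0, basis$L, basis$L)
  }
  wts <- 1 / se_beta^2
  XtWX <- crossprod(design * sqrt(wts))
  A <- XtWX + lambda * R
  sol <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(sol)) {
    if (lambda == 0)
      stop("singular system at lambda = 0; add a roughness penalty or reduce the basis size")
    stop("singular penalized system")
  }
  b_hat <- drop(sol %*% crossprod(design, wts * beta_hat))
  cov_b <- sol %*% XtWX %*% sol    # sandwich under eps_k ~ N(0, se^2)
  structure(list(b_hat = b_hat, cov_b = cov_b, lambda = lambda, m = m,
                 design = design, se_beta = se_beta, beta_hat = beta_hat,
                 R = R, basis = basis, model = model),
            class = "sss_fit")
}

#' Fit the scalar-on-function regression
#'
#' Generalized-least-squares fit of the stratum Wald ratios on the basis
#' inner products, with optional roughness penalty:
#' `b_hat = (X' S^-1 X + lambda R)^-1 X' S^-1 beta_hat`, where `S` is the
#' diagonal matrix of squared Wald-ratio standard errors. The coefficient
#' covariance is the sandwich
#' `(X'S^-1X + lambda R)^-1 X'S^-1X (X'S^-1X + lambda R)^-1`.
#'
#' @param summaries an `sss_summaries` object.
#' @param basis a [basis_spec()].
#' @param lambda penalty weight (>= 0; `"gcv"` selects it by generalized
#'   cross-validation over `lambda_grid`).
#' @param m penalty derivative order (default 2).
#' @param lambda_grid grid for GCV selection (default log-spaced
#'   `10^-4 ... 10^4`, 17 points).
#' @return an object of class `sss_fit`.
#' @export
fit_sof <- function(summaries, basis, lambda = 0, m = 2L,
                    lambda_grid = 10^seq(-4, 4, length.out = 17)) {
  design <- build_sof_design(summaries, basis)
  tab <- summaries$summaries
  if (identical(lambda, "gcv"))
    lambda <- select_lambda_gcv(summaries, basis, m, lambda_grid,
                                design = design)$lambda
  fit_weighted_basis(design, tab$beta_hat, tab$se_beta, basis, lambda, m,
                     model = "sof")
}

#' Fit the scalar-on-scalar regression
#'
#' Identical algebra to [fit_sof()] with the functional inner products
#' replaced by the basis evaluated at the stratum exposure means:
#' `A[k, l] = phi_l(xbar_k)`. This approximation is accurate when strata are
#' narrow (the stratum weight concentrates near its mean), and is the
#' convention of most current nonlinear Mendelian randomization practice.
#'
#' @inheritParams fit_sof
#' @return an object of class `sss_fit`.
#' @export
fit_sos <- function(summaries, basis, lambda = 0, m = 2L,
                    lambda_grid = 10^seq(-4, 4, length.out = 17)) {
  stopifnot(inherits(summaries, "sss_summaries"))
  tab <- summaries$summaries
  design <- basis_eval(basis, tab$xbar)
  if (identical(lambda, "gcv"))
    lambda <- select_lambda_gcv(summaries, basis, m, lambda_grid,
                                design = design)$lambda
  fit_weighted_basis(design, tab$beta_hat, tab$se_beta, basis, lambda, m,
                     model = "sos")
}

#' @export
print.sss_fit <- function(x, ...) {
  cat(sprintf("<sss_fit> %s, L = %d basis functions, lambda = %g\n",
              toupper(x$model), length(x$b_hat), x$lambda))
  print(round(x$b_hat, 4))
  invisible(x)
}

#' Select the penalty weight by generalized cross-validation
#'
#' Minimizes `GCV(lambda) = (K / (K - tr(H))) * (SSE / (K - tr(H)))` on the
#' whitened system, where `H` is the hat matrix
#' `S^-1/2 X (X'S^-1X + lambda R)^-1 X' S^-1/2` and SSE the whitened residual
#' sum of squares. Grid values with `tr(H) >= K` are skipped with a warning.
#'
#' @inheritParams fit_sof
#' @param design optional precomputed design matrix.
#' @return list with `lambda` (the minimizer) and `table`
#'   (lambda, trace, sse, gcv per grid value).
#' @export
select_lambda_gcv <- function(summaries, basis, m = 2L,
                              lambda_grid = 10^seq(-4, 4, length.out = 17),
                              design = NULL) {
  stopifnot(length(lambda_grid) >= 1L, all(lambda_grid >= 0))
  if (is.null(design)) design <- build_sof_design(summaries, basis)
  tab <- summaries$summaries
  K <- nrow(design)
  R <- basis_penalty(basis, m)
  w <- 1 / tab$se_beta
  Xw <- design * w
  yw <- tab$beta_hat * w
  rows <- lapply(lambda_grid, function(lam) {
    A <- crossprod(Xw) + lam * R
    sol <- tryCatch(solve(A), error = function(e) NULL)
    if (is.null(sol)) return(data.frame(lambda = lam, trace = NA, sse = NA,
                                        gcv = NA))
    H <- Xw %*% sol %*% t(Xw)
    tr <- sum(diag(H))
    if (tr >= K) {
      warning(sprintf("lambda = %g skipped: tr(H) >= K", lam))
      return(data.frame(lambda = lam, trace = tr, sse = NA, gcv = NA))
    }
    sse <- sum((yw - drop(H %*% yw))^2)
    data.frame(lambda = lam, trace = tr, sse = sse,
               gcv = (K / (K - tr)) * (sse / (K - tr)))
  })
  table <- do.call(rbind, rows)
  ok <- which(is.finite(table$gcv))
  if (!length(ok)) stop("GCV undefined on the whole grid")
  list(lambda = table$lambda[ok[which.min(table$gcv[ok])]], table = table)
}

#' Reconstruct the effect curve from a fitted basis model
#'
#' Computes the effect intensity `h'(x) = phi(x)' b_hat`, the effect shape
#' `h(x) = [int_0^x phi(s) ds]' b_hat` (so `h(0) = 0` exactly), and pointwise
#' Wald-type 95 percent confidence bands from the coefficient covariance by
#' the delta method.
#'
#' @param fit an `sss_fit` from [fit_sof()] or [fit_sos()].
#' @param grid exposure grid.
#' @param level band level (default 0.95).
#' @return a data frame of class `sss_effect_curve` with columns `grid`, `h`,
#'   `h_prime`, `lower`, `upper` and attribute `band_kind = "confidence"`.
#' @export
effect_curve <- function(fit, grid, level = 0.95) {
  stopifnot(inherits(fit, "sss_fit"))
  Phi <- basis_eval(fit$basis, grid)
  Ad <- basis_antideriv(fit$basis, grid)
  h <- drop(Ad %*% fit$b_hat)
  hp <- drop(Phi %*% fit$b_hat)
  se_h <- sqrt(pmax(rowSums((Ad %*% fit$cov_b) * Ad), 0))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- data.frame(grid = grid, h = h, h_prime = hp,
                    lower = h - zq * se_h, upper = h + zq * se_h)
  attr(out, "band_kind") <- "confidence"
  class(out) <- c("sss_effect_curve", "data.frame")
  out
}
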