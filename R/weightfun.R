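#' Step-function weight on the exposure domain
#'
#' A `weight_fn` represents the instrument-implied exposure weight
#' W(x) = Cov(Z, I\{X >= x\}) / Cov(Z, X) as an exact step function:
#' strictly increasing breakpoints `breaks` (length m) and constant heights
#' `heights` (length m - 1) on the intervals between consecutive breakpoints.
#' All integrals against polynomials and indicator tails are computed by exact
#' piecewise integration, never by grid sampling, so the normalisation
#' \eqn{\int W = 1} holds to machine precision.
#'
#' @param breaks numeric, strictly increasing breakpoints.
#' @param heights numeric of length `length(breaks) - 1`, step heights
#'   (units: 1/exposure).
#' @return an object of class `weight_fn`.
#' @export
weight_fn <- function(breaks, heights) {
  stopifnot(is.numeric(breaks), is.numeric(heights),
            length(breaks) >= 2L, length(heights) == length(breaks) - 1L)
  if (any(diff(breaks) <= 0)) stop("'breaks' must be strictly increasing")
  structure(list(breaks = as.numeric(breaks), heights = as.numeric(heights)),
            class = "weight_fn")
}

#' @export
print.weight_fn <- function(x, ...) {
  cat(sprintf("<weight_fn> %d steps on [%.4g, %.4g], integral = %.6f\n",
              length(x$heights), x$breaks[1L], x$breaks[length(x$breaks)],
              wf_integral(x)))
  invisible(x)
}

#' Exact integral of a step weight function
#'
#' @param w a [weight_fn].
#' @return \eqn{\int W(x) dx} over the full support.
#' @export
wf_integral <- function(w) sum(diff(w$breaks) * w$heights)

#' Exact tail mass of a step weight function
#'
#' Computes \eqn{\int_t^\infty W(x) dx}, the inner product of W with the
#' indicator basis function I\{x >= t\}. Thresholds below the support return
#' the full integral; thresholds above it return 0.
#'
#' @param w a [weight_fn].
#' @param t numeric vector of thresholds.
#' @return numeric vector of tail masses.
#' @export
wf_tail <- function(w, t) {
  b <- w$breaks; h <- w$heights
  # cumulative integral from the right at each breakpoint
  seg <- diff(b) * h
  tail_at_break <- c(rev(cumsum(rev(seg))), 0)  # length m, tail from b[j]
  vapply(t, function(ti) {
    if (ti <= b[1L]) return(tail_at_break[1L])
    if (ti >= b[length(b)]) return(0)
    j <- findInterval(ti, b)  # b[j] <= ti < b[j+1]
    tail_at_break[j + 1L] + (b[j + 1L] - ti) * h[j]
  }, numeric(1))
}

#' Exact polynomial moments of a step weight function
#'
#' @param w a [weight_fn].
#' @param p nonnegative integer power.
#' @return \eqn{\int x^p W(x) dx} computed piecewise in closed form.
#' @export
wf_moment <- function(w, p) {
  b <- w$breaks
  sum(w$heights * (b[-1L]^(p + 1) - b[-length(b)]^(p + 1)) / (p + 1))
}

# Exact inner product <f, W> for f polynomial on each piece of `w` once the
# steps are subdivided at `cuts`; Gauss-Legendre with `nodes` points is exact
# for polynomial degree 2*nodes - 1.
wf_inner_fun <- function(w, f, cuts = NULL, nodes = 7L) {
  gl <- gauss_legendre(nodes)
  b <- w$breaks
  pts <- sort(unique(c(b, cuts[cuts > b[1L] & cuts < b[length(b)]])))
  lo <- pts[-length(pts)]; hi <- pts[-1L]
  mid <- (lo + hi) / 2; half <- (hi - lo) / 2
  hseg <- w$heights[findInterval(mid, b)]
  tot <- 0
  for (q in seq_len(nodes)) {
    xq <- mid + gl$x[q] * half
    tot <- tot + sum(gl$w[q] * half * hseg * f(xq))
  }
  tot
}

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigen method.
gauss_legendre <- function(n) {
  if (n == 1L) return(list(x = 0, w = 2))
  i <- seq_len(n - 1L)
  bsub <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- bsub
  J[cbind(i + 1L, i)] <- bsub
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1L, ]^2)
}

#' Empirical weight-function estimate for a stratum
#'
#' Estimates W_k(x) = Cov(Z, I\{X >= x\}) / Cov(Z, X) within a stratum as a
#' right-continuous step function with breakpoints at the stratum's sorted
#' distinct exposure values. The sample covariances use denominator n - 1.
#' By the telescoping identity Cov(Z, X - min X) = sum of interval
#' contributions, the returned step function integrates to exactly 1.
#'
#' @param z instrument values within the stratum.
#' @param x exposure values within the stratum.
#' @return a [weight_fn].
#' @export
estimate_weight_function <- function(z, x) {
  n <- length(x)
  stopifnot(length(z) == n, n >= 3L)
  if (stats::sd(z) == 0) stop("constant instrument within stratum")
  czx <- stats::cov(z, x)
  if (abs(czx) < .Machine$double.eps * max(abs(x)) * n)
    stop("instrument unassociated with exposure within stratum")
  o <- order(x)
  xs <- x[o]; zs <- z[o]
  ux <- unique(xs)
  if (length(ux) < 2L) stop("need at least 2 distinct exposure values")
  # Cov(Z, I{X >= v}) for v just above each distinct value:
  # suffix sums of z over observations with X >= next distinct value.
  last_idx <- cumsum(tabulate(match(xs, ux), nbins = length(ux)))
  suffix_z <- rev(cumsum(rev(zs)))           # sum of z with index >= i
  zbar <- mean(z)
  m <- length(ux)
  # for interval (ux[j], ux[j+1]], indicator selects X >= ux[j+1]
  sz <- c(suffix_z, 0)[last_idx + 1L][-m]     # sum z over X >= ux[j+1]
  cnt <- (n - last_idx)[-m]                   # count of X >= ux[j+1]
  cov_ind <- (sz - cnt * zbar) / (n - 1)
  weight_fn(ux, cov_ind / czx)
}

#' Parametric (normal) weight function
#'
#' Under joint normality of instrument and exposure the weight function equals
#' the exposure density, so it can be summarised by the exposure mean and
#' standard deviation alone. Returns the N(mean, sd^2) density discretised as
#' a fine step function and renormalised to integrate to exactly 1.
#'
#' @param mean exposure mean.
#' @param sd exposure standard deviation (> 0).
#' @param n_steps number of steps (default 2000).
#' @param width half-width of the support in standard deviations (default 6).
#' @return a [weight_fn].
#' @export
parametric_weight_function <- function(mean, sd, n_steps = 2000L, width = 6) {
  stopifnot(sd > 0, n_steps >= 10L)
  breaks <- seq(mean - width * sd, mean + width * sd, length.out = n_steps + 1L)
  mids <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  h <- stats::dnorm(mids, mean, sd)
  w <- weight_fn(breaks, h)
  w$heights <- w$heights / wf_integral(w)
  w
}

#' Evaluate a step weight function on a grid (plotting export)
#'
#' @param w a [weight_fn].
#' @param x numeric vector of evaluation points.
#' @return step-function values (0 outside the support; right-continuous on
#'   the half-open intervals `(b_j, b_(j+1)]`).
#' @export
wf_eval <- function(w, x) {
  b <- w$breaks
  j <- findInterval(x, b, left.open = TRUE)
  out <- numeric(length(x))
  inside <- j >= 1L & j <= length(w$heights)
  out[inside] <- w$heights[j[inside]]
  out
}
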