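#' Validate and coerce an instrument-exposure-outcome table
#'
#' Drops rows with missing Z, X or Y (with a message reporting the count) and
#' checks the minimal structure needed for stratified IV analysis.
#'
#' @param data data frame with columns `Z`, `X`, `Y` (an `id` column is added
#'   if absent; extra columns are preserved untouched).
#' @param K intended number of strata (used for the distinct-exposure check).
#' @return the cleaned data frame.
#' @export
as_iv_data <- function(data, K = 2L) {
  stopifnot(is.data.frame(data), all(c("Z", "X", "Y") %in% names(data)))
  keep <- stats::complete.cases(data[, c("Z", "X", "Y")])
  if (any(!keep)) {
    message(sum(!keep), " row(s) with missing Z/X/Y dropped")
    data <- data[keep, , drop = FALSE]
  }
  if (!"id" %in% names(data)) data$id <- seq_len(nrow(data))
  if (length(unique(data$Z)) < 2L)
    stop("need at least 2 distinct instrument values")
  if (length(unique(data$X)) < K)
    stop("need at least K distinct exposure values")
  data
}

new_strata <- function(data, labels, method, K, dropped) {
  data$stratum <- labels
  structure(list(data = data, labels = labels, method = method,
                 K = as.integer(K), dropped = as.integer(dropped)),
            class = "sss_strata")
}

#' @export
print.sss_strata <- function(x, ...) {
  cat(sprintf("<sss_strata> method = %s, K = %d, n = %d (%d dropped)\n",
              x$method, x$K, sum(!is.na(x$labels)), x$dropped))
  invisible(x)
}

#' Residual (prediction) stratification
#'
#' Fits the instrument-exposure curve by least squares of `t^{-1}(X)` on Z
#' (linear in Z), predicts each individual's counterfactual exposure at the
#' reference instrument level z0 = 0 as
#' `t(fhat(0) + t^{-1}(X) - fhat(Z))`, and assigns strata as equal-size
#' quantile groups of the prediction. Stratifying on this predicted
#' counterfactual -- rather than on the observed exposure, which is a collider
#' of instrument and confounders -- preserves within-stratum exchangeability.
#'
#' Remainder rows (when n is not divisible by K) are allocated to the lowest
#' strata. Ties in the prediction are broken by original row order.
#'
#' @param data data frame with columns `Z`, `X`, `Y`.
#' @param K number of strata (>= 2, at most n/2).
#' @param transform exposure transformation `t`: `"identity"` or `"log"`
#'   (requires all X > 0).
#' @return an object of class `sss_strata`.
#' @export
residual_stratify <- function(data, K, transform = c("identity", "log")) {
  transform <- match.arg(transform)
  K <- as.integer(K)
  if (K < 2L) stop("K must be at least 2")
  data <- as_iv_data(data, K)
  n <- nrow(data)
  if (K > n / 2) stop("K exceeds n/2; too many strata for the sample size")
  tx <- switch(transform, identity = data$X,
               log = {
                 if (any(data$X <= 0)) stop("log transform requires X > 0")
                 log(data$X)
               })
  vz <- stats::var(data$Z)
  czx <- stats::cov(data$Z, tx)
  if (abs(czx) < .Machine$double.eps * n * max(1, stats::sd(tx)) * max(1, sqrt(vz)))
    stop("instrument unassociated with exposure")
  alpha <- czx / vz
  pred0 <- tx - alpha * data$Z            # counterfactual at z0 = 0 (t-scale)
  xhat0 <- switch(transform, identity = pred0, log = exp(pred0))
  sizes <- rep(n %/% K, K)
  extra <- n %% K
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- rep(seq_len(K), times = sizes)[rank(xhat0, ties.method = "first")]
  new_strata(data, labels, "residual", K, dropped = 0L)
}

#' Doubly-ranked (matching) stratification
#'
#' Sorts rows by the instrument (stable), forms `floor(n/K)` pre-strata of
#' exactly K consecutive rows each (trailing remainder rows are dropped and
#' counted), ranks the exposure within each pre-stratum, and assigns stratum
#' k = within-pre-stratum exposure rank. Each stratum then contains one member
#' per complete pre-stratum, so stratum exposure means are strictly increasing
#' for continuous exposures. Valid under the rank-preserving assumption: an
#' individual's counterfactual exposure keeps its population rank across
#' instrument levels.
#'
#' Ties in both rankings are broken by original row order (stable sort), so
#' the assignment is deterministic.
#'
#' @param data data frame with columns `Z`, `X`, `Y`.
#' @param K number of strata (>= 2, at most n).
#' @return an object of class `sss_strata`.
#' @export
doubly_ranked_stratify <- function(data, K) {
  K <- as.integer(K)
  if (K < 2L) stop("K must be at least 2")
  data <- as_iv_data(data, K)
  n <- nrow(data)
  if (n < K) stop("n < K: not enough rows for the requested strata")
  n_pre <- n %/% K
  dropped <- n - n_pre * K
  ord <- order(data$Z)                     # stable for numeric keys
  kept <- ord[seq_len(n_pre * K)]
  pre <- rep(seq_len(n_pre), each = K)
  xr <- stats::ave(data$X[kept], pre,
                   FUN = function(v) rank(v, ties.method = "first"))
  labels <- rep(NA_integer_, n)
  labels[kept] <- as.integer(xr)
  new_strata(data, labels, "doubly_ranked", K, dropped = dropped)
}

#' Retained rows of a stratification, with their stratum labels
#'
#' @param strata an `sss_strata` object.
#' @return the data frame restricted to retained rows, including the
#'   `stratum` column.
#' @export
strata_data <- function(strata) {
  strata$data[!is.na(strata$labels), , drop = FALSE]
}
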