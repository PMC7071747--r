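#' Influence-trimming map for outlier-robust Cox regression
#'
#' The trimming map is
#' \deqn{A_{\beta, M}(t, z) = M - \min(M,\; t\, e^{\beta' z}),}
#' a nonnegative weight that decreases in the product of time and relative
#' hazard and vanishes once \eqn{t e^{\beta' z} \ge M}.  Using \eqn{A} both on
#' each event's own contribution and inside the risk-set means
#' ("double-trimming") keeps the estimating equation Fisher-consistent for the
#' Cox model parameters while bounding the influence of extreme observations.
#'
#' @param M Positive truncation bound.
#' @param beta_ref Coefficient vector at which the map is frozen.
#' @param quantile Order-statistic level used to pick `M` (recorded for
#'   reporting; `NA` if `M` was supplied directly).
#' @return An object of class `"influence_map"`.
#' @seealso [select_truncation()], [influence_weight()]
#' @export
influence_map <- function(M, beta_ref, quantile = NA_real_) {
  stopifnot(is.numeric(M), length(M) == 1, is.finite(M), M > 0,
            is.numeric(beta_ref))
  structure(list(M = M, quantile = quantile, beta_ref = unname(beta_ref)),
            class = "influence_map")
}

#' @export
print.influence_map <- function(x, ...) {
  cat("Influence-trimming map A(t, z) = M - min(M, t * exp(beta_ref' z))\n")
  cat(sprintf("  M = %g%s\n", x$M,
              if (is.na(x$quantile)) "" else sprintf(" (quantile %.3g)", x$quantile)))
  cat("  beta_ref =", format(x$beta_ref, digits = 6), "\n")
  invisible(x)
}

#' Evaluate the influence-trimming weight
#'
#' @param map An [influence_map()].
#' @param t Positive time(s).
#' @param z Covariate values: a vector (one covariate, recycled against `t`)
#'   or a matrix with one row per observation.
#' @return Nonnegative weights in `[0, M]`; exactly 0 where
#'   \eqn{t e^{\beta' z} \ge M}.  An overflowing linear predictor is treated
#'   as \eqn{+\infty} (weight 0).
#' @export
influence_weight <- function(map, t, z) {
  stopifnot(inherits(map, "influence_map"), all(t > 0))
  z <- if (is.matrix(z)) z else matrix(z, ncol = length(map$beta_ref))
  u <- t * guarded_exp(drop(z %*% map$beta_ref))
  a <- pmax(0, map$M - pmin(map$M, u))
  a[!is.finite(u)] <- 0
  a
}

#' Select the truncation bound M from the data
#'
#' `M` is the \eqn{\lceil q n \rceil}-th order statistic of the per-subject
#' products \eqn{t_i e^{\beta' z_i}}, computed over all subjects in the
#' analyzed dataset (events and censored alike); the default level is the
#' 95th percentile.  No interpolation is used: `M` is always an observed
#' sample value.
#'
#' @inheritParams risk_set_sums
#' @param quantile Order-statistic level in (0, 1]; default 0.95.
#' @return The truncation bound, a positive scalar.
#' @export
select_truncation <- function(data, beta, quantile = 0.95,
                              time = "time", status = "status", covariates,
                              weights = NULL) {
  sdata <- as_survival_data(data, time, status, covariates, weights)
  stopifnot(length(quantile) == 1, quantile > 0, quantile <= 1)
  cn <- attr(sdata, "covariates")
  stopifnot(length(beta) == length(cn))
  Z <- as.matrix(sdata[, cn, drop = FALSE])
  u <- sdata$time * guarded_exp(drop(Z %*% beta))
  sort(u)[ceiling(quantile * length(u))]
}
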