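#' Weighted risk-set sums at a single time
#'
#' Computes the building blocks of the (weighted) Cox partial likelihood at a
#' time `t`:
#' \deqn{S^{(0)}(\beta,t) = \sum_{j: t_j \ge t} c_j e^{\beta' z_j}, \quad
#'       S^{(1)} = \sum c_j z_j e^{\beta' z_j}, \quad
#'       S^{(2)} = \sum c_j z_j z_j' e^{\beta' z_j},}
#' together with the weighted covariate mean \eqn{\bar z = S^{(1)}/S^{(0)}}.
#' The per-subject multiplier \eqn{c_j} (`combined_weight`) selects the
#' weighting regime: all 1 for the plain partial likelihood, the influence
#' weight \eqn{A(t, z_j)} for the trimmed estimator, or
#' \eqn{w_j A(t, z_j)} when sampling weights are also in play.
#'
#' Risk-set membership uses the closed condition \eqn{t_j \ge t}, so tied
#' subjects share risk sets (Breslow convention).
#'
#' @param data A `survival_data` object (or a data frame together with the
#'   column arguments of [survival_data()]).
#' @param beta Coefficient vector, one entry per covariate.
#' @param t Time at which to evaluate the sums (strictly positive).
#' @param combined_weight Optional nonnegative per-subject multiplier
#'   \eqn{c_j}; default all 1.
#' @inheritParams survival_data
#' @return A list with elements `s0` (scalar), `s1` (vector), `s2` (matrix)
#'   and `zbar` (vector).
#' @examples
#' df <- data.frame(time = c(3, 2, 1), status = c(1, 1, 1), z = c(0, 1, 2))
#' sdat <- survival_data(df, covariates = "z")
#' risk_set_sums(sdat, beta = log(2), t = 1)
#' @export
risk_set_sums <- function(data, beta, t, combined_weight = NULL,
                          time = "time", status = "status", covariates,
                          weights = NULL) {
  sdata <- as_survival_data(data, time, status, covariates, weights)
  cn <- attr(sdata, "covariates")
  n <- nrow(sdata)
  stopifnot(length(beta) == length(cn), length(t) == 1, t > 0)
  cw <- combined_weight %||% rep(1, n)
  stopifnot(length(cw) == n, all(cw >= 0), all(is.finite(cw)))

  Z <- as.matrix(sdata[, cn, drop = FALSE])
  at_risk <- sdata$time >= t
  u <- cw * at_risk * exp(drop(Z %*% beta))
  s0 <- sum(u)
  if (s0 <= 0)
    abort(sprintf("degenerate risk set at time %g: no subject at risk with positive weight (total trimming or empty risk set)", t))
  s1 <- drop(crossprod(Z, u))
  s2 <- crossprod(Z, Z * u)
  list(s0 = s0, s1 = setNames(s1, cn), s2 = s2, zbar = setNames(s1 / s0, cn))
}

#' Score and information of a weighted partial-likelihood estimating equation
#'
#' Reference (pure R) evaluation of
#' \deqn{U(\beta) = \sum_{i: \Delta_i = 1} e_i \left[ z_i - \bar z(\beta, t_i) \right]}
#' and the corresponding information
#' \deqn{I(\beta) = \sum_{i: \Delta_i = 1} e_i \left[ S^{(2)}/S^{(0)} - \bar z \bar z' \right](\beta, t_i),}
#' where \eqn{e_i} (`event_weight`) multiplies subject i's own event term
#' (e.g. \eqn{w_i A(t_i, z_i)}) and `riskset_weight` gives, for an event time
#' `t`, the multiplier of every risk-set member (e.g. \eqn{w_j A(t, z_j)} —
#' the influence weight is evaluated at the EVENT time with the member's
#' covariates).  Sums run over events only; censored subjects contribute
#' through risk sets.
#'
#' This is the transparent counterpart of the compiled engine used by
#' [cox_newton()]; the two agree to machine precision and are cross-checked in
#' the test suite.
#'
#' @inheritParams risk_set_sums
#' @param event_weight Nonnegative per-subject vector; default all 1.
#' @param riskset_weight `NULL` (all 1) or a function `f(t)` returning the
#'   nonnegative per-subject multiplier vector at event time `t`.
#' @return A list with elements `score` (vector) and `information` (matrix).
#' @export
cox_score <- function(data, beta, event_weight = NULL, riskset_weight = NULL,
                      time = "time", status = "status", covariates,
                      weights = NULL) {
  sdata <- as_survival_data(data, time, status, covariates, weights)
  cn <- attr(sdata, "covariates")
  p <- length(cn)
  n <- nrow(sdata)
  stopifnot(length(beta) == p)
  ew <- event_weight %||% rep(1, n)
  stopifnot(length(ew) == n, all(ew >= 0))

  Z <- as.matrix(sdata[, cn, drop = FALSE])
  score <- numeric(p)
  info <- matrix(0, p, p)
  for (i in which(sdata$status == 1)) {
    if (ew[i] == 0) next
    cw <- if (is.null(riskset_weight)) NULL else riskset_weight(sdata$time[i])
    rs <- risk_set_sums(sdata, beta, t = sdata$time[i], combined_weight = cw)
    score <- score + ew[i] * (Z[i, ] - rs$zbar)
    info <- info + ew[i] * (rs$s2 / rs$s0 - tcrossprod(rs$zbar))
  }
  dimnames(info) <- list(cn, cn)
  list(score = setNames(score, cn), information = info)
}
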