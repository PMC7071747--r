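#' Outlier-robust, sampling-weighted Cox proportional hazards fit
#'
#' The main fitting interface.  `method = "robust"` (default) runs the full
#' pipeline: (1) plain unweighted Cox fit as the starting point; (2) three
#' alternating updates of the trimming map \eqn{A(t,z) = M - \min(M, t
#' e^{\beta' z})} and the trimmed coefficients, with `M` the chosen order
#' statistic (default 95th percentile) of \eqn{t_i e^{\beta' z_i}} and
#' sampling weights deliberately excluded; (3) one final solve of the doubly
#' weighted score \eqn{\sum_i w_i A(t_i, z_i)[z_i - \bar z_{wr}(\beta, t_i)] = 0}
#' with the map frozen; (4) the doubly-weighted sandwich variance.
#' `method = "plain"` fits the ordinary (possibly sampling-weighted) Cox
#' partial likelihood with the same engine.
#'
#' @inheritParams risk_set_sums
#' @param method `"robust"` (influence-trimmed) or `"plain"`.
#' @param trim_quantile Order-statistic level for the truncation bound `M`
#'   (robust method only); default 0.95.
#' @param n_outer Number of (map, coefficient) alternations; default 3.
#' @param m_cap Optional fixed upper bound on `M`; default none.
#' @param residual_type Residual convention for the sandwich variance; see
#'   [sandwich_variance()].
#' @param variance `"auto"` (default): model-based inverse-information
#'   variance for plain fits with constant sampling weights, sandwich
#'   otherwise; `"sandwich"` or `"model"` to force a choice (`"model"` is only
#'   available for plain fits).
#' @param conf_level Confidence level for Wald intervals; default 0.95.
#' @param bonferroni Optional number of tests `m`; intervals and p-value
#'   threshold are widened to level `1 - (1 - conf_level)/m`.
#' @param tol,max_iter Newton controls.
#' @return An object of class `"coxrob"`; see [tidy.coxrob()] and
#'   [glance.coxrob()] for tabular views.
#' @examples
#' set.seed(7)
#' pop <- generate_population(sim_config(n_population = 800, n_replicates = 1))
#' fit <- coxrob(pop, covariates = "exposure")
#' tidy(fit, exponentiate = TRUE)
#' @export
coxrob <- function(data, time = "time", status = "status", covariates,
                   weights = NULL, method = c("robust", "plain"),
                   trim_quantile = 0.95, n_outer = 3L, m_cap = NULL,
                   residual_type = c("score", "direct"),
                   variance = c("auto", "sandwich", "model"),
                   conf_level = 0.95, bonferroni = NULL,
                   tol = 1e-9, max_iter = 50L) {
  method <- match.arg(method)
  residual_type <- match.arg(residual_type)
  variance <- match.arg(variance)
  sdata <- as_survival_data(data, time, status, covariates, weights)
  require_events(sdata)
  cn <- attr(sdata, "covariates")
  n <- nrow(sdata)
  constant_w <- length(unique(sdata$sampling_weight)) == 1

  if (method == "plain") {
    fit <- cox_newton(sdata, tol = tol, max_iter = max_iter)
    map <- NULL
    influence_values <- rep(1, n)
  } else {
    tf <- fit_trimmed(sdata, trim_quantile = trim_quantile, n_outer = n_outer,
                      m_cap = m_cap, tol = tol, max_iter = max_iter)
    map <- tf$map
    fit <- if (constant_w) tf else {
      refit_weighted(sdata, map, beta_init = unname(tf$beta),
                     tol = tol, max_iter = max_iter)
    }
    Z <- as.matrix(sdata[, cn, drop = FALSE])
    influence_values <- influence_weight(map, sdata$time, Z)
  }

  use_model_var <- switch(variance,
    auto = method == "plain" && constant_w,
    model = {
      if (method != "plain")
        abort('variance = "model" is only available for plain fits')
      TRUE
    },
    sandwich = FALSE)

  if (use_model_var) {
    # inverse information on the unit-weight scale (constant weights cancel)
    unit <- sdata
    unit$sampling_weight <- rep(1, n)
    si <- cox_score(unit, beta = unname(fit$beta))
    covariance <- solve(si$information)
    vtype <- "model"
  } else {
    vc <- sandwich_variance(sdata, map = map, beta = unname(fit$beta),
                            residual_type = residual_type)
    covariance <- vc$sandwich
    vtype <- paste0("sandwich (", residual_type, ")")
  }
  dimnames(covariance) <- list(cn, cn)
  std_errors <- sqrt(pmax(diag(covariance), 0))

  level <- effective_level(conf_level, bonferroni)
  structure(list(
    coefficients = fit$beta,
    covariance = covariance,
    std_errors = setNames(std_errors, cn),
    variance_type = vtype,
    residual_type = residual_type,
    method = method,
    map = map,
    truncation_M = if (is.null(map)) NA_real_ else map$M,
    trim_quantile = if (is.null(map)) NA_real_ else trim_quantile,
    influence_values = influence_values,
    converged = fit$converged,
    score_norm = fit$score_norm,
    n_iter = fit$n_iter,
    n = n,
    n_events = sum(sdata$status == 1),
    sum_weights = sum(sdata$sampling_weight),
    conf_level = level,
    diagnostics = tibble::tibble(
      time = sdata$time, status = sdata$status,
      influence = influence_values,
      rel_hazard_time = sdata$time *
        guarded_exp(drop(as.matrix(sdata[, cn, drop = FALSE]) %*%
                           unname(fit$beta)))),
    call = match.call()
  ), class = "coxrob")
}

effective_level <- function(conf_level, bonferroni = NULL) {
  stopifnot(conf_level > 0, conf_level < 1)
  if (is.null(bonferroni)) return(conf_level)
  stopifnot(bonferroni >= 1)
  1 - (1 - conf_level) / bonferroni
}

#' @export
coef.coxrob <- function(object, ...) object$coefficients

#' @export
vcov.coxrob <- function(object, ...) object$covariance

#' @export
print.coxrob <- function(x, digits = 4, ...) {
  cat(sprintf("%s Cox fit (coxtrim)\n",
              if (x$method == "robust") "Outlier-robust" else "Plain"))
  cat(sprintf("  n = %d, events = %d, sum of weights = %g\n",
              x$n, x$n_events, x$sum_weights))
  if (x$method == "robust")
    cat(sprintf("  truncation M = %g (quantile %.3g), %.1f%% fully trimmed\n",
                x$truncation_M, x$trim_quantile,
                100 * mean(x$influence_values == 0)))
  cat(sprintf("  variance: %s; converged: %s (score max-norm %.2g)\n",
              x$variance_type, x$converged, x$score_norm))
  tab <- tidy(x)
  print(as.data.frame(tab), digits = digits, row.names = FALSE)
  invisible(x)
}
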