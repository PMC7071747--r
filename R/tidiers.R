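#' Tidy a coxrob fit
#'
#' @param x A [coxrob()] fit.
#' @param exponentiate Report hazard ratios (`exp(beta)`) instead of log
#'   hazard ratios; default `FALSE`.
#' @param conf.int Include Wald confidence bounds at the fit's (possibly
#'   Bonferroni-widened) level; default `TRUE`.
#' @param ... Unused.
#' @return A tibble with one row per covariate: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`, and `conf.low`/`conf.high` when
#'   requested.  Standard errors are always on the log-hazard scale.
#' @export
tidy.coxrob <- function(x, exponentiate = FALSE, conf.int = TRUE, ...) {
  est <- unname(x$coefficients)
  se <- unname(x$std_errors)
  zstat <- est / se
  out <- tibble::tibble(
    term = names(x$coefficients),
    estimate = est,
    std.error = se,
    statistic = zstat,
    p.value = 2 * pnorm(-abs(zstat)))
  if (conf.int) {
    q <- qnorm(1 - (1 - x$conf_level) / 2)
    out$conf.low <- est - q * se
    out$conf.high <- est + q * se
  }
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    if (conf.int) {
      out$conf.low <- exp(out$conf.low)
      out$conf.high <- exp(out$conf.high)
    }
  }
  out
}

#' One-row summary of a coxrob fit
#'
#' @param x A [coxrob()] fit.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `n_events`, `sum_weights`, `method`,
#'   `trim_quantile`, `truncation_M`, `fraction_trimmed`, `converged`,
#'   `score_norm`, `n_iter`.
#' @export
glance.coxrob <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_events = x$n_events,
    sum_weights = x$sum_weights,
    method = x$method,
    trim_quantile = x$trim_quantile,
    truncation_M = x$truncation_M,
    fraction_trimmed = mean(x$influence_values == 0),
    converged = x$converged,
    score_norm = x$score_norm,
    n_iter = x$n_iter)
}

#' Influence-weight diagnostic plot for a coxrob fit
#'
#' Plots each subject's product \eqn{t_i e^{\hat\beta' z_i}} against the
#' influence weight \eqn{A(t_i, z_i)} it received, marking the truncation
#' bound `M`.  Fully trimmed subjects sit on the zero line to the right of
#' `M`; for a plain fit all weights are 1.
#'
#' @param object A [coxrob()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coxrob <- function(object, ...) {
  d <- object$diagnostics
  d$event <- factor(ifelse(d$status == 1, "event", "censored"),
                    levels = c("event", "censored"))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$rel_hazard_time,
                                       y = .data$influence,
                                       colour = .data$event)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::labs(x = "t * exp(beta' z)", y = "influence weight A(t, z)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.na(object$truncation_M))
    p <- p + ggplot2::geom_vline(xintercept = object$truncation_M,
                                 linetype = "dashed")
  p
}

#' @importFrom rlang .data
NULL
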