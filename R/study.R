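# Monte-Carlo driver: per-replicate fits and Table-style aggregation.

fit_one_estimator <- function(dat, method, quantile, weighted, compute_se,
                              plain_init = NULL) {
  if (method == "cox") {
    fit <- cox_newton(dat, use_weights = weighted)
    beta <- unname(fit$beta)[1]
    se <- NA_real_
    if (compute_se) {
      if (weighted) {
        vc <- sandwich_variance(dat, map = NULL, beta = unname(fit$beta))
        se <- sqrt(diag(vc$sandwich))[1]
      } else {
        # model-based: the fit's information is already on the unit-weight scale
        se <- sqrt(diag(solve(fit$information)))[1]
      }
    }
    list(estimate = beta, se = se, converged = fit$converged)
  } else {
    tf <- fit_trimmed(dat, trim_quantile = quantile)
    fit <- if (weighted) {
      refit_weighted(dat, tf$map, beta_init = unname(tf$beta))
    } else tf
    beta <- unname(fit$beta)[1]
    se <- NA_real_
    if (compute_se) {
      vc <- sandwich_variance(dat, map = tf$map, beta = unname(fit$beta))
      se <- sqrt(diag(vc$sandwich))[1]
    }
    list(estimate = beta, se = se, converged = fit$converged)
  }
}

run_replicate <- function(config, rep_seed, compute_se) {
  set.seed(rep_seed)
  pop <- generate_population(config)
  est <- config$estimators
  need_sample <- any(est$block == "sample")
  samp <- if (need_sample) draw_case_cohort(pop, config$subcohort_size) else NULL
  rows <- vector("list", nrow(est))
  for (r in seq_len(nrow(est))) {
    dat <- if (est$block[r] == "sample") samp else pop
    res <- tryCatch(
      fit_one_estimator(dat, est$method[r], est$quantile[r],
                        weighted = est$block[r] == "sample",
                        compute_se = compute_se),
      error = function(e) list(estimate = NA_real_, se = NA_real_,
                               converged = FALSE))
    rows[[r]] <- tibble::tibble(
      block = est$block[r], method = est$method[r], quantile = est$quantile[r],
      estimate = res$estimate, se = res$se,
      converged = isTRUE(res$converged),
      sample_size = nrow(dat))
  }
  dplyr::bind_rows(rows)
}

#' Run the Monte-Carlo simulation study
#'
#' For each replicate: generate a population ([generate_population()]), draw
#' a case-cohort sample when any sample-block estimator is configured
#' ([draw_case_cohort()]), fit every configured estimator — unweighted on the
#' population, sampling-weighted on the sample — and record the coefficient
#' and its standard error.  Replicate-level seeds are derived once from
#' `config$seed`, so results are bit-identical for a fixed seed regardless of
#' the number of workers, and failed fits are excluded from the means and
#' counted.
#'
#' @param config A [sim_config()].
#' @param workers Number of parallel workers (forked; results are reduced in
#'   replicate order so the worker count never changes the output).
#' @param compute_se Also compute per-fit standard errors (model-based for
#'   the unweighted plain Cox fit, sandwich otherwise); default `TRUE`.
#' @return A tibble of class `"sim_summary"` with one row per estimator:
#'   `block`, `method`, `quantile`, `mean_coef`, `mean_se`, `empirical_sd`,
#'   `n_used`, `n_failed`, `mean_sample_size`, plus the scenario columns
#'   `contamination_fraction` and `contamination_mean`.  The per-replicate
#'   results are attached as attribute `"replicates"`.
#' @export
run_study <- function(config, workers = 1L, compute_se = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max, config$n_replicates)
  one <- function(i) run_replicate(config, rep_seeds[i], compute_se)
  reps <- if (workers > 1L) {
    parallel::mclapply(seq_len(config$n_replicates), one,
                       mc.cores = workers, mc.preschedule = TRUE)
  } else {
    lapply(seq_len(config$n_replicates), one)
  }
  per_rep <- dplyr::bind_rows(reps, .id = "replicate")
  summ <- per_rep |>
    dplyr::group_by(.data$block, .data$method, .data$quantile) |>
    dplyr::summarise(
      mean_coef = mean(.data$estimate[.data$converged]),
      mean_se = mean(.data$se[.data$converged]),
      empirical_sd = sd(.data$estimate[.data$converged]),
      n_used = sum(.data$converged),
      n_failed = sum(!.data$converged),
      mean_sample_size = mean(.data$sample_size),
      .groups = "drop") |>
    dplyr::mutate(
      contamination_fraction = config$contamination_fraction,
      contamination_mean = config$contamination_mean)
  attr(summ, "replicates") <- per_rep
  attr(summ, "config") <- config
  class(summ) <- c("sim_summary", class(summ))
  summ
}

#' Comparison plot of estimator means from a simulation summary
#'
#' Dot plot of mean coefficient estimates per estimator and block, with a
#' horizontal reference line at the true log hazard ratio.
#'
#' @param object A `"sim_summary"` from [run_study()] (or several row-bound
#'   together, provided the true hazard ratio is the same).
#' @param true_loghr Reference value; defaults to the generating value stored
#'   in the attached config.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sim_summary <- function(object, true_loghr = NULL, ...) {
  cfg <- attr(object, "config")
  true_loghr <- true_loghr %||%
    (if (is.null(cfg)) NA_real_ else log(cfg$hr_per_unit))
  d <- as.data.frame(object)
  d$estimator <- ifelse(d$method == "cox", "Cox PL",
                        sprintf("robust%02.0f", 100 * d$quantile))
  d$scenario <- sprintf("%g%% @ mean %g", 100 * d$contamination_fraction,
                        d$contamination_mean)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$estimator,
                                       y = .data$mean_coef,
                                       shape = .data$block,
                                       colour = .data$scenario)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4),
                        size = 2) +
    ggplot2::labs(x = NULL, y = "mean coefficient estimate",
                  shape = NULL, colour = NULL) +
    ggplot2::theme_minimal()
  if (is.finite(true_loghr))
    p <- p + ggplot2::geom_hline(yintercept = true_loghr, linetype = "dashed")
  p
}
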