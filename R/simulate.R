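#' Configuration for the contaminated case-cohort simulation study
#'
#' Bundles the data-generating parameters for a Monte-Carlo study of Cox
#' estimators under exposure contamination and case-cohort sampling.  The
#' defaults describe the reference scenario used throughout the package:
#' a population of 6000 subjects; exposure Normal(12, 8^2) clipped to
#' [0, 100] (mirroring immune-cell fractions measured as percentages);
#' event times Weibull with shape 1 and scale \eqn{1000 \cdot e^{-\ln(HR_x) x}}
#' so the true log hazard ratio per exposure unit is \eqn{\ln(1.25) = 0.223};
#' censoring Weibull with shape 1 and scale 2 (event fraction about 8%);
#' contamination replacing a fraction of exposures with draws from a shifted
#' Normal (same SD); a case-cohort subcohort of 600 non-cases.
#'
#' @param n_population Population size per replicate.
#' @param hr_per_unit True hazard ratio per unit of exposure.
#' @param event_scale_base,event_shape Weibull parameters of the event-time
#'   distribution; the scale for subject i is
#'   `event_scale_base * exp(-log(hr_per_unit) * x_i)`.
#' @param censor_scale,censor_shape Weibull parameters of the censoring-time
#'   distribution.
#' @param exposure_mean,exposure_sd Mean and SD of the clean exposure.
#' @param exposure_bounds Length-2 vector; exposures are clipped to this range.
#' @param contamination_fraction Fraction of subjects whose exposure is
#'   replaced (in `[0, 1)`).
#' @param contamination_mean Mean of the replacement exposure distribution
#'   (SD is `exposure_sd`).
#' @param subcohort_size Number of non-cases sampled into the case-cohort
#'   subcohort.
#' @param n_replicates Number of Monte-Carlo replicates.
#' @param seed Integer seed controlling all randomness of [run_study()].
#' @param estimators Tibble with columns `method` (`"cox"` or `"robust"`),
#'   `quantile` (truncation quantile, `NA` for `"cox"`), and `block`
#'   (`"population"` for unweighted fits on the full population, `"sample"`
#'   for sampling-weighted fits on the case-cohort sample).  Default:
#'   plain Cox plus robust at quantiles 0.90 and 0.95, in both blocks.
#' @param truncation How exposure bounds are enforced: `"clip"` (values set to
#'   the bound; default) or `"resample"` (rejection sampling).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_population = 6000, hr_per_unit = 1.25,
                       event_scale_base = 1000, event_shape = 1,
                       censor_scale = 2, censor_shape = 1,
                       exposure_mean = 12, exposure_sd = 8,
                       exposure_bounds = c(0, 100),
                       contamination_fraction = 0, contamination_mean = 24,
                       subcohort_size = 600, n_replicates = 1000, seed = 1,
                       estimators = default_estimators(),
                       truncation = c("clip", "resample")) {
  truncation <- match.arg(truncation)
  cfg <- list(n_population = as.integer(n_population),
              hr_per_unit = hr_per_unit,
              event_scale_base = event_scale_base, event_shape = event_shape,
              censor_scale = censor_scale, censor_shape = censor_shape,
              exposure_mean = exposure_mean, exposure_sd = exposure_sd,
              exposure_bounds = exposure_bounds,
              contamination_fraction = contamination_fraction,
              contamination_mean = contamination_mean,
              subcohort_size = as.integer(subcohort_size),
              n_replicates = as.integer(n_replicates),
              seed = as.integer(seed),
              estimators = estimators, truncation = truncation)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  pos <- c("hr_per_unit", "event_scale_base", "event_shape", "censor_scale",
           "censor_shape", "exposure_sd")
  for (f in pos)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      abort(sprintf("`%s` must be a positive number", f))
  if (cfg$contamination_fraction < 0 || cfg$contamination_fraction >= 1)
    abort("`contamination_fraction` must be in [0, 1)")
  if (cfg$n_population < 2 || cfg$subcohort_size < 1 || cfg$n_replicates < 1)
    abort("`n_population`, `subcohort_size` and `n_replicates` must be positive")
  if (length(cfg$exposure_bounds) != 2 ||
      cfg$exposure_bounds[1] >= cfg$exposure_bounds[2])
    abort("`exposure_bounds` must be an increasing pair")
  est <- cfg$estimators
  if (!all(c("method", "quantile", "block") %in% names(est)))
    abort("`estimators` needs columns method, quantile, block")
  if (!all(est$method %in% c("cox", "robust")) ||
      !all(est$block %in% c("population", "sample")))
    abort("`estimators`: method must be cox/robust, block population/sample")
  invisible(cfg)
}

#' @rdname sim_config
#' @param quantiles Truncation quantiles for the robust estimators.
#' @param blocks Which blocks to include.
#' @export
default_estimators <- function(quantiles = c(0.90, 0.95),
                               blocks = c("population", "sample")) {
  base <- dplyr::bind_rows(
    tibble::tibble(method = "cox", quantile = NA_real_),
    tibble::tibble(method = "robust", quantile = quantiles))
  tidyr_crossing <- expand.grid(i = seq_len(nrow(base)), block = blocks,
                                stringsAsFactors = FALSE)
  out <- base[tidyr_crossing$i, ]
  out$block <- tidyr_crossing$block
  tibble::as_tibble(out[order(match(out$block, c("population", "sample"))), ])
}

clip_or_resample <- function(x, bounds, mean, sd, how) {
  if (how == "clip") return(pmin(pmax(x, bounds[1]), bounds[2]))
  bad <- which(x < bounds[1] | x > bounds[2])
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < bounds[1] | x[bad] > bounds[2]]
  }
  x
}

#' Generate one population replicate
#'
#' Draws a population under the configured data-generating process:
#' clean exposures from a clipped Normal; event times from a Weibull whose
#' scale is \eqn{1000 \cdot e^{-\ln(HR_x)\, x}} with `x` the CLEAN exposure;
#' censoring from an exposure-independent Weibull; observed time
#' `pmin(T, C)` and status `T < C`.  Contamination then replaces the
#' *recorded* exposure of a random fraction of subjects with draws from a
#' shifted Normal — after the event times were generated — so outliers carry
#' no causal signal, which is exactly the situation that biases untrimmed
#' estimators toward the null.
#'
#' Uses the current RNG state; seed management belongs to the caller (or to
#' [run_study()], which derives one seed per replicate).
#'
#' @param config A [sim_config()].
#' @return A `survival_data` tibble with columns `time`, `status`,
#'   `sampling_weight` (all 1), `exposure`, and a logical `contaminated`
#'   column flagging replaced exposures.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_population
  x_clean <- clip_or_resample(
    rnorm(n, config$exposure_mean, config$exposure_sd),
    config$exposure_bounds, config$exposure_mean, config$exposure_sd,
    config$truncation)
  scale_i <- config$event_scale_base *
    exp(-log(config$hr_per_unit) * x_clean)
  T_event <- rweibull(n, shape = config$event_shape, scale = scale_i)
  C_cens <- rweibull(n, shape = config$censor_shape, scale = config$censor_scale)
  x_obs <- x_clean
  contaminated <- rep(FALSE, n)
  m <- floor(config$contamination_fraction * n)
  if (m > 0) {
    idx <- sample.int(n, m)
    x_obs[idx] <- clip_or_resample(
      rnorm(m, config$contamination_mean, config$exposure_sd),
      config$exposure_bounds, config$contamination_mean, config$exposure_sd,
      config$truncation)
    contaminated[idx] <- TRUE
  }
  out <- tibble::tibble(time = pmin(T_event, C_cens),
                        status = as.integer(T_event < C_cens),
                        sampling_weight = 1,
                        exposure = x_obs,
                        contaminated = contaminated)
  attr(out, "covariates") <- "exposure"
  class(out) <- c("survival_data", class(out))
  out
}

#' Draw a case-cohort sample with inverse-probability weights
#'
#' Keeps every subject with an event (sampling weight 1, since cases are
#' sampled with probability 1) plus a simple random sample without
#' replacement of `subcohort_size` non-cases, each weighted by the inverse of
#' its realized sampling probability, `(number of non-cases)/subcohort_size`.
#' The weighted non-case count therefore reproduces the population non-case
#' count exactly, and the weights sum to the population size.
#'
#' @param population A `survival_data` tibble (e.g. from
#'   [generate_population()]).
#' @param subcohort_size Number of non-cases to sample.
#' @return A `survival_data` tibble with updated `sampling_weight`.
#' @export
draw_case_cohort <- function(population, subcohort_size = 600) {
  stopifnot(inherits(population, "survival_data"))
  is_case <- population$status == 1
  n0 <- sum(!is_case)
  if (subcohort_size > n0)
    abort(sprintf("subcohort_size (%d) exceeds the number of non-cases (%d)",
                  subcohort_size, n0))
  keep_nc <- sample(which(!is_case), subcohort_size)
  out <- population[c(which(is_case), sort(keep_nc)), ]
  out$sampling_weight <- ifelse(out$status == 1, 1, n0 / subcohort_size)
  attr(out, "covariates") <- attr(population, "covariates")
  class(out) <- class(population)
  out
}
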