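#' Assemble and validate a survival dataset
#'
#' Builds the canonical per-subject table used by every fitting function:
#' observed time \eqn{t_i = \min(T_i, C_i)}, event indicator \eqn{\Delta_i},
#' one or more numeric covariates \eqn{z_i}, and a positive sampling weight
#' \eqn{w_i} (the inverse of the probability that subject \eqn{i} was included
#' in the analyzed sample; 1 for a complete cohort).
#'
#' @param data A data frame with one row per subject.
#' @param time Name of the column holding observed times (strictly positive).
#' @param status Name of the event indicator column (0 = censored, 1 = event).
#' @param covariates Character vector of covariate column names, in order.
#' @param weights Optional name of a sampling-weight column; when `NULL` all
#'   weights are 1.
#' @return A tibble of class `"survival_data"` with columns `time`, `status`,
#'   `sampling_weight` and the covariate columns, plus a `"covariates"`
#'   attribute listing the covariate names.
#' @examples
#' df <- data.frame(t = c(2, 5, 3), d = c(1, 0, 1), x = c(0.4, -1, 2))
#' survival_data(df, time = "t", status = "d", covariates = "x")
#' @export
survival_data <- function(data, time = "time", status = "status",
                          covariates, weights = NULL) {
  stopifnot(is.data.frame(data))
  cols <- c(time, status, covariates, weights)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0)
    abort(paste0("column(s) not found in `data`: ",
                 paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(cols))
    abort("`time`, `status`, `covariates` and `weights` must name distinct columns")

  tt <- as.numeric(data[[time]])
  dd <- data[[status]]
  if (is.logical(dd)) dd <- as.integer(dd)
  dd <- as.numeric(dd)
  ww <- if (is.null(weights)) rep(1, nrow(data)) else as.numeric(data[[weights]])
  Z <- as.matrix(as.data.frame(lapply(data[covariates], as.numeric)))
  colnames(Z) <- covariates

  if (any(!is.finite(tt)) || any(tt <= 0))
    abort("all times must be finite and strictly positive")
  if (!all(dd %in% c(0, 1)))
    abort("`status` must contain only 0 (censored) and 1 (event)")
  if (any(!is.finite(ww)) || any(ww <= 0))
    abort("all sampling weights must be finite and strictly positive")
  if (any(!is.finite(Z)))
    abort("covariates must contain only finite values")

  out <- tibble::tibble(time = tt, status = as.integer(dd), sampling_weight = ww)
  for (v in covariates) out[[v]] <- Z[, v]
  attr(out, "covariates") <- covariates
  class(out) <- c("survival_data", class(out))
  out
}

# matrix view used by the engine; sorts by time and keeps the permutation
sd_unpack <- function(sdata, sort = TRUE) {
  cn <- attr(sdata, "covariates")
  ord <- if (sort) order(sdata$time) else seq_len(nrow(sdata))
  list(time = sdata$time[ord],
       status = as.integer(sdata$status[ord]),
       Z = as.matrix(sdata[ord, cn, drop = FALSE]),
       w = sdata$sampling_weight[ord],
       covariates = cn, order = ord, n = nrow(sdata))
}

as_survival_data <- function(data, time, status, covariates, weights) {
  if (inherits(data, "survival_data") && missing(covariates)) return(data)
  survival_data(data, time = time, status = status,
                covariates = covariates, weights = weights)
}

require_events <- function(sdata) {
  if (sum(sdata$status == 1) < 1)
    abort("at least one event is required to fit a model")
  invisible(sdata)
}

#' Winsorize a numeric vector at k standard deviations from its mean
#'
#' Clips values to `[mean - k * sd, mean + k * sd]`, with the mean and sample
#' standard deviation (denominator n - 1) computed once from the input.  A
#' common pre-processing comparator for exposures with heavy tails; unlike
#' influence trimming it looks only at the covariate value, not at the
#' time-to-event.
#'
#' @param x Numeric vector.
#' @param k Positive number of standard deviations; default 4.
#' @return `x` with out-of-range values replaced by the nearer bound.  Vectors
#'   with fewer than two distinct values are returned unchanged.
#' @examples
#' winsorize(c(0, 0, 0, 0, 100), k = 1)
#' @export
winsorize <- function(x, k = 4) {
  stopifnot(is.numeric(x), is.numeric(k), length(k) == 1, k > 0)
  if (length(unique(x[is.finite(x)])) < 2) return(x)
  m <- mean(x)
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(x)
  pmin(pmax(x, m - k * s), m + k * s)
}
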