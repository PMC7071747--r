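# Damped Newton solver for the weighted / trimmed partial-likelihood score.
#
# The engine centers covariates at their column means before exponentiation so
# exp(beta'z) cannot overflow for exposures on scales like [0, 100]; all
# reported quantities (score, information, beta) are shift-invariant, so the
# centering is invisible to callers.  The trimming map is evaluated on the
# original covariate scale (eref, M are computed there) — the engine receives
# eref as data and never re-exponentiates the reference linear predictor.

EXP_GUARD <- 700  # exp() overflow guard on linear predictors

guarded_exp <- function(x) exp(pmin(x, EXP_GUARD))

# per-subject A(t_i, z_i) and risk-set ingredients for a frozen map
trim_pieces <- function(up, trim) {
  if (is.null(trim)) {
    return(list(trimmed = FALSE, M = Inf, eref = rep(1, up$n),
                a_own = rep(1, up$n)))
  }
  eref <- guarded_exp(drop(up$Z %*% trim$beta_ref))
  u <- up$time * eref
  a_own <- pmax(0, trim$M - pmin(trim$M, u))
  a_own[!is.finite(u)] <- 0
  list(trimmed = TRUE, M = trim$M, eref = eref, a_own = a_own)
}

newton_core <- function(up, trim = NULL, use_weights = FALSE, beta_init = NULL,
                        tol = 1e-9, max_iter = 50L, max_halvings = 20L) {
  p <- ncol(up$Z)
  center <- colMeans(up$Z)
  Zc <- sweep(up$Z, 2, center)
  tp <- trim_pieces(up, trim)
  wv <- if (use_weights) up$w else rep(1, up$n)
  ew <- wv * tp$a_own
  if (all(ew[up$status == 1] == 0))
    abort("degenerate trimming: every event has influence weight zero")

  eval_score <- function(beta) {
    res <- .cox_score_info_cpp(up$time, up$status, Zc, beta, wv, ew,
                               tp$trimmed, tp$M, tp$eref)
    if (!res$ok)
      abort(sprintf("degenerate risk set at event time %g: no subject at risk with positive weight", res$bad_time))
    res
  }

  beta <- beta_init %||% numeric(p)
  cur <- eval_score(beta)
  fn <- max(abs(cur$score))
  converged <- fn <= tol
  n_iter <- 0L
  while (!converged && n_iter < max_iter) {
    step <- tryCatch(solve(cur$information, cur$score),
                     error = function(e) abort("singular information matrix in Newton step"))
    lambda <- 1
    for (h in seq_len(max_halvings)) {
      cand <- beta + lambda * step
      cand_eval <- eval_score(cand)
      cand_fn <- max(abs(cand_eval$score))
      if (is.finite(cand_fn) && cand_fn < fn) break
      lambda <- lambda / 2
    }
    beta <- cand
    cur <- cand_eval
    fn <- cand_fn
    n_iter <- n_iter + 1L
    converged <- is.finite(fn) && fn <= tol
  }
  list(beta = setNames(beta, up$covariates), converged = converged,
       score_norm = fn, n_iter = n_iter,
       score = setNames(drop(cur$score), up$covariates),
       information = structure(cur$information,
                               dimnames = list(up$covariates, up$covariates)))
}

#' Solve a weighted partial-likelihood estimating equation by damped Newton
#'
#' Finds the root of the (optionally trimmed and sampling-weighted) Cox score
#' using Newton-Raphson with step halving: a step is halved (up to 20 times)
#' whenever it fails to decrease the max-norm of the score.  The trimming map,
#' when supplied, is frozen — its reference coefficients and truncation bound
#' do not change during the solve.
#'
#' @inheritParams risk_set_sums
#' @param trim `NULL` for the untrimmed score, or an [influence_map()] whose
#'   \eqn{A(t, z)} multiplies every contribution as in the trimmed estimating
#'   equation.
#' @param use_weights Should the sampling weights multiply the score terms?
#'   Default `TRUE` (with unit weights this changes nothing).
#' @param beta_init Starting values; default all 0.
#' @param tol Convergence tolerance on the max-norm of the score.
#' @param max_iter Maximum Newton iterations.
#' @return A list with `beta`, `converged`, `score_norm`, `n_iter`, `score`
#'   and `information`.  Non-convergence is flagged (with a warning), not an
#'   error; a singular information matrix is an error.
#' @export
cox_newton <- function(data, time = "time", status = "status", covariates,
                       weights = NULL, trim = NULL, use_weights = TRUE,
                       beta_init = NULL, tol = 1e-9, max_iter = 50L) {
  sdata <- as_survival_data(data, time, status, covariates, weights)
  require_events(sdata)
  stopifnot(tol > 0)
  up <- sd_unpack(sdata)
  fit <- newton_core(up, trim = trim, use_weights = use_weights,
                     beta_init = beta_init, tol = tol, max_iter = max_iter)
  if (!fit$converged)
    warn(sprintf("Newton did not converge in %d iterations (score max-norm %.3g)",
                 fit$n_iter, fit$score_norm))
  fit
}
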