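# Independent oracles and fixture builders (no package internals).

# Exact log partial likelihood, Breslow ties, one covariate; brute force only.
log_partial_lik <- function(beta, time, status, z) {
  sum(vapply(which(status == 1), function(i) {
    beta * z[i] - log(sum(exp(beta * z[time >= time[i]])))
  }, numeric(1)))
}

# two-stage dense grid maximizer of the log partial likelihood
grid_maximizer <- function(time, status, z, lo = -10, hi = 10) {
  g1 <- seq(lo, hi, by = 0.01)
  v1 <- vapply(g1, log_partial_lik, numeric(1), time = time, status = status, z = z)
  b1 <- g1[which.max(v1)]
  g2 <- seq(b1 - 0.02, b1 + 0.02, by = 1e-5)
  v2 <- vapply(g2, log_partial_lik, numeric(1), time = time, status = status, z = z)
  g2[which.max(v2)]
}

# tie-free random survival dataset with known-ish effect
random_dataset <- function(n, p = 1, seed) {
  set.seed(seed)
  Z <- matrix(rnorm(n * p), n, p)
  colnames(Z) <- paste0("x", seq_len(p))
  beta <- seq(0.3, by = 0.2, length.out = p)
  tt <- rexp(n, rate = exp(Z %*% beta))
  cc <- rexp(n, rate = 0.4)
  out <- data.frame(time = pmin(tt, cc), status = as.integer(tt < cc))
  cbind(out, as.data.frame(Z))
}

toy6 <- function() {
  data.frame(time = c(1, 2, 3, 4, 5, 6),
             status = c(1, 1, 0, 1, 1, 0),
             z = c(1, 0, 1, 0, 1, 0))
}

small_config <- function(...) {
  args <- utils::modifyList(list(n_population = 600, subcohort_size = 80,
                                 n_replicates = 2, seed = 99), list(...))
  do.call(sim_config, args)
}
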