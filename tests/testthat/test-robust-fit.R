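test_that("with no observation trimmed the estimator tracks the plain fit", {
  # compress times so t * exp(beta'z) is nearly constant, then inflate M:
  # A is then almost constant and the trimmed root approaches the plain one
  set.seed(12)
  n <- 60
  df <- data.frame(time = 1 + 1e-4 * runif(n),
                   status = rbinom(n, 1, 0.7), z = rnorm(n, sd = 0.3))
  plain <- cox_newton(df, covariates = "z")
  map <- influence_map(M = 1e6, beta_ref = unname(plain$beta))
  trimmed <- cox_newton(df, covariates = "z", trim = map, use_weights = FALSE)
  expect_equal(unname(trimmed$beta), unname(plain$beta), tolerance = 1e-3)
})

test_that("unit (or constant) sampling weights reduce the refit to the trimmed fit", {
  df <- random_dataset(120, p = 1, seed = 23)
  tf <- fit_trimmed(df, covariates = "x1", trim_quantile = 0.95)
  b_unit <- refit_weighted(df, tf$map, beta_init = unname(tf$beta),
                           covariates = "x1")
  expect_equal(unname(b_unit$beta), unname(tf$beta), tolerance = 1e-8)

  df$w <- rep(4.2, nrow(df))
  b_const <- refit_weighted(df, tf$map, beta_init = unname(tf$beta),
                            covariates = "x1", weights = "w")
  expect_equal(unname(b_const$beta), unname(tf$beta), tolerance = 1e-8)
})

test_that("the returned estimate is a root of the doubly-weighted score", {
  df <- random_dataset(150, p = 1, seed = 29)
  df$w <- runif(150, 0.5, 10)
  sdat <- survival_data(df, covariates = "x1", weights = "w")
  tf <- fit_trimmed(sdat, trim_quantile = 0.9)
  fit <- refit_weighted(sdat, tf$map, beta_init = unname(tf$beta))
  expect_true(fit$converged)
  expect_lte(fit$score_norm, 1e-9)

  # independent evaluation of the doubly-weighted score via the R reference
  Z <- as.matrix(df["x1"])
  a_own <- influence_weight(tf$map, df$time, Z)
  ref <- cox_score(sdat, beta = unname(fit$beta),
                   event_weight = df$w * a_own,
                   riskset_weight = function(t)
                     df$w * influence_weight(tf$map, t, Z))
  expect_lte(max(abs(ref$score)), 1e-9)
})

test_that("influence weights stay in [0, M] across all outer iterations", {
  df <- random_dataset(100, p = 1, seed = 37)
  for (q in c(0.9, 0.95)) {
    tf <- fit_trimmed(df, covariates = "x1", trim_quantile = q)
    a <- influence_weight(tf$map, df$time, as.matrix(df["x1"]))
    expect_true(all(a >= 0 & a <= tf$map$M))
    expect_true(any(a == 0))            # something is trimmed at q < 1
  }
})

test_that("coxrob pipeline ties the pieces together", {
  set.seed(41)
  cfg <- sim_config(n_population = 1500, contamination_fraction = 0.05,
                    contamination_mean = 24, n_replicates = 1, seed = 41)
  pop <- generate_population(cfg)
  samp <- draw_case_cohort(pop, 300)
  fit <- coxrob(samp, covariates = "exposure", weights = "sampling_weight",
                trim_quantile = 0.95)
  expect_s3_class(fit, "coxrob")
  expect_true(fit$converged)
  expect_equal(fit$truncation_M, fit$map$M)
  expect_equal(fit$n_events, sum(samp$status))
  expect_equal(fit$influence_values,
               influence_weight(fit$map, samp$time, as.matrix(samp["exposure"])))

  td <- tidy(fit)
  expect_equal(td$term, "exposure")
  expect_equal(td$estimate, unname(fit$coefficients))
  gl <- glance(fit)
  expect_equal(gl$n, nrow(samp))

  plain <- coxrob(samp, covariates = "exposure", weights = "sampling_weight",
                  method = "plain")
  expect_true(all(plain$influence_values == 1))
  expect_true(is.na(plain$truncation_M))
})

test_that("trimming catches a sizeable share of contaminated observations", {
  # qualitative check: under 5% contamination, full trimming at the subject's
  # own time should flag contaminated subjects far above chance, without
  # being anywhere near perfect
  set.seed(49)
  cfg <- sim_config(contamination_fraction = 0.05, contamination_mean = 36,
                    n_replicates = 1, seed = 49)
  pop <- generate_population(cfg)
  tf <- fit_trimmed(pop, trim_quantile = 0.95)
  ts <- trimming_summary(pop, tf$map, truth = pop$contaminated)
  expect_equal(ts$fraction_trimmed, 0.05, tolerance = 0.1)
  expect_gt(ts$sensitivity, 0.2)
  expect_lt(ts$sensitivity, 0.95)
  expect_gt(ts$precision, 0.2)
})

test_that("standard errors are invariant to rescaling the sampling weights", {
  df <- random_dataset(130, p = 1, seed = 43)
  df$w <- runif(130, 0.5, 6)
  f1 <- coxrob(df, covariates = "x1", weights = "w", trim_quantile = 0.95)
  df$w <- 11 * df$w
  f2 <- coxrob(df, covariates = "x1", weights = "w", trim_quantile = 0.95)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
  expect_equal(f1$std_errors, f2$std_errors, tolerance = 1e-6)
})

test_that("trimming diagnostics report sensitivity and precision", {
  df <- random_dataset(50, p = 1, seed = 47)
  sdat <- survival_data(df, covariates = "x1")

  # map so large nothing is trimmed: sensitivity undefined (NA), fraction 0
  map_wide <- influence_map(M = 1e9, beta_ref = 0)
  ts0 <- trimming_summary(sdat, map_wide, truth = rep(c(TRUE, FALSE), 25))
  expect_equal(ts0$fraction_trimmed, 0)
  expect_true(is.na(ts0$precision))
  expect_equal(ts0$sensitivity, 0)

  # perfect detection: flags equal to the trimmed set
  tf <- fit_trimmed(sdat, trim_quantile = 0.9)
  ts1 <- trimming_summary(sdat, tf$map,
                          truth = influence_weight(tf$map, df$time,
                                                   as.matrix(df["x1"])) == 0)
  expect_equal(ts1$sensitivity, 1)
  expect_equal(ts1$precision, 1)
  expect_equal(nrow(ts1$per_subject), 50)
})
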