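test_that("configuration is validated", {
  expect_error(sim_config(contamination_fraction = 1), "contamination_fraction")
  expect_error(sim_config(exposure_sd = 0), "positive")
  expect_error(sim_config(exposure_bounds = c(5, 1)), "increasing")
  cfg <- sim_config()
  expect_equal(cfg$n_population, 6000L)
  expect_equal(cfg$hr_per_unit, 1.25)
  expect_equal(cfg$subcohort_size, 600L)
})

test_that("population generation respects bounds, flags, and the null case", {
  set.seed(71)
  cfg <- sim_config(n_population = 3000, contamination_fraction = 0)
  pop <- generate_population(cfg)
  expect_equal(nrow(pop), 3000)
  expect_false(any(pop$contaminated))
  expect_true(all(pop$exposure >= 0 & pop$exposure <= 100))
  expect_true(all(pop$time > 0))
  expect_true(all(pop$status %in% 0:1))
  expect_true(all(pop$sampling_weight == 1))

  cfg2 <- sim_config(n_population = 3000, contamination_fraction = 0.05,
                     contamination_mean = 24)
  pop2 <- generate_population(cfg2)
  expect_equal(sum(pop2$contaminated), floor(0.05 * 3000))
  expect_gt(mean(pop2$exposure[pop2$contaminated]),
            mean(pop2$exposure[!pop2$contaminated]))

  # null case: exposure unrelated to hazard
  cfg0 <- sim_config(n_population = 4000, hr_per_unit = 1)
  pop0 <- generate_population(cfg0)
  fit0 <- coxrob(pop0, covariates = "exposure", method = "plain")
  expect_lt(abs(unname(fit0$coefficients)) / fit0$std_errors, 4)
})

test_that("the event fraction matches its closed-form expectation", {
  # P(event) = E_x[ r(x) / (r(x) + 1/censor_scale) ], r(x) = exp(log(HR) x)/1000,
  # by independent numerical integration over the clipped Normal(12, 8^2)
  h <- function(x) exp(log(1.25) * x) / 1000
  integrand <- function(x) h(x) / (h(x) + 0.5) * dnorm(x, 12, 8)
  p_mid <- integrate(integrand, 0, 100)$value
  p_lo <- pnorm(0, 12, 8) * h(0) / (h(0) + 0.5)
  p_hi <- (1 - pnorm(100, 12, 8)) * h(100) / (h(100) + 0.5)
  p_expected <- p_mid + p_lo + p_hi

  set.seed(73)
  cfg <- sim_config()
  frac <- mean(replicate(3, mean(generate_population(cfg)$status)))
  expect_equal(frac, p_expected, tolerance = 0.08)
  expect_equal(p_expected, 0.08, tolerance = 0.05)
})

test_that("case-cohort samples carry exact inverse-probability weights", {
  set.seed(79)
  cfg <- sim_config(n_population = 2000)
  pop <- generate_population(cfg)
  samp <- draw_case_cohort(pop, subcohort_size = 300)
  n0 <- sum(pop$status == 0)

  expect_equal(sum(samp$status == 1), sum(pop$status == 1))  # all cases kept
  expect_equal(sum(samp$status == 0), 300)
  expect_equal(unique(samp$sampling_weight[samp$status == 1]), 1)
  expect_equal(unique(samp$sampling_weight[samp$status == 0]), n0 / 300)
  expect_equal(sum(samp$sampling_weight), nrow(pop))          # exact total
  expect_equal(sum(samp$sampling_weight[samp$status == 0]), n0)

  expect_error(draw_case_cohort(pop, subcohort_size = n0 + 1),
               "exceeds the number of non-cases")
})

test_that("contaminated fractions carry through to the sample on average", {
  set.seed(83)
  cfg <- sim_config(n_population = 4000, contamination_fraction = 0.10)
  fr <- replicate(4, {
    pop <- generate_population(cfg)
    mean(draw_case_cohort(pop, 600)$contaminated)
  })
  expect_equal(mean(fr), 0.10, tolerance = 0.02)
})

test_that("the study driver is deterministic and aggregates correctly", {
  cfg <- small_config(estimators = tibble::tibble(
    method = c("cox", "robust"), quantile = c(NA, 0.95),
    block = c("population", "sample")))
  s1 <- run_study(cfg)
  s2 <- run_study(cfg)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_equal(s1$n_used + s1$n_failed, rep(cfg$n_replicates, nrow(s1)))
  expect_true(all(s1$mean_sample_size >= cfg$subcohort_size))

  # single replicate: summary equals the replicate's own estimates
  cfg1 <- small_config(n_replicates = 1, estimators = tibble::tibble(
    method = "cox", quantile = NA_real_, block = "population"))
  s <- run_study(cfg1)
  reps <- attr(s, "replicates")
  expect_equal(s$mean_coef, reps$estimate)
  expect_equal(s$empirical_sd, NA_real_)
})

test_that("worker count does not change the study output", {
  cfg <- small_config(n_replicates = 4, estimators = tibble::tibble(
    method = "cox", quantile = NA_real_, block = "population"))
  s1 <- run_study(cfg, workers = 1)
  s2 <- run_study(cfg, workers = 2)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})
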