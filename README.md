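# coxtrim

Outlier-robust Cox proportional hazards regression with
inverse-probability-of-sampling weights.

## The problem

Cox regression estimates the association between an exposure and a
time-to-event outcome.  Two things routinely go wrong in observational
studies:

* **Influential outliers** — when some covariate values come from a process
  unrelated to the outcome (assay artifacts, a distinct biological
  subpopulation), they carry no causal signal and drag the estimated log
  hazard ratio toward zero.  Skewed exposures such as immune-cell fractions
  make this common.
* **Outcome-dependent sampling** — in a case-cohort design the exposure is
  measured only on all cases plus a random subcohort, so fits must weight
  subjects by inverse sampling probabilities to target population
  associations.

`coxtrim` fits an estimator that handles both at once.  The trimmed,
sampling-weighted estimating equation is

```
sum_i  w_i A(t_i, z_i) [ z_i - zbar_wr(beta, t_i) ]  =  0,
A(t, z) = M - min(M, t exp(beta' z)),
```

where `w_i` is the sampling weight, `A` is an influence weight that vanishes
once the product of time and relative hazard exceeds a truncation bound `M`
(an order statistic of the `t_i exp(beta' z_i)`, default the 95th
percentile), and `zbar_wr` is the doubly-weighted risk-set mean of the
covariates.  `A` and `beta` are estimated by three alternating iterations
*without* the sampling weights — so the influence weights flag outliers, not
large sampling weights — and the weights enter in one final solve with the
map frozen.  Standard errors come from a doubly-weighted sandwich estimator.
See the methods vignette (`vignettes/robust-weighted-cox.Rmd`) for the full
account, including the two implemented residual conventions.

## Worked example

A bundled synthetic case-cohort sample (402 of 2000 subjects: all 152 cases
plus 250 non-cases with weight 7.4) was generated with a true hazard ratio
of 1.25 per exposure unit and 5% of exposures replaced by draws from a
distribution with tripled mean:

```r
library(coxtrim)
dat <- read.csv(system.file("extdata", "synthetic_casecohort.csv",
                            package = "coxtrim"))

tidy(coxrob(dat, covariates = "exposure", weights = "sampling_weight",
            method = "plain"), exponentiate = TRUE)
#>   term     estimate std.error statistic  p.value conf.low conf.high
#> 1 exposure     1.07    0.0107      6.44 1.17e-10     1.05      1.09

fit <- coxrob(dat, covariates = "exposure", weights = "sampling_weight",
              trim_quantile = 0.95)
print(fit)
#> Outlier-robust Cox fit (coxtrim)
#>   n = 402, events = 152, sum of weights = 2000
#>   truncation M = 44.1015 (quantile 0.95), 5.2% fully trimmed
#>   variance: sandwich (score); converged: TRUE (score max-norm 2.5e-13)
#>      term estimate std.error statistic  p.value conf.low conf.high
#>  exposure   0.1167   0.01006      11.6 4.11e-31  0.09699    0.1364
```

The plain weighted fit reports a hazard ratio of 1.07 per unit; the trimmed
fit, which gave zero influence to 5.2% of subjects (those with the largest
`t exp(beta'z)` products), reports 1.12 — substantially closer to the
generating value of 1.25.  This is the expected pattern: contamination
attenuates the plain estimate, and trimming recovers part of the loss.
`autoplot(fit)` shows each subject's influence weight against
`t exp(beta'z)` with the truncation bound marked; `trimming_summary()`
reports which subjects were fully trimmed.

The Monte-Carlo machinery behind the package's validation is exported too:

```r
cfg <- sim_config(contamination_fraction = 0.05, contamination_mean = 24,
                  n_replicates = 100, seed = 1)
run_study(cfg)          # mean estimates / SEs per estimator and block
```

A command-line interface wraps both paths (`inst/cli/coxtrim fit ...` and
`... simulate --config scenarios.yaml`); see `?cli_fit` and `?cli_simulate`.

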