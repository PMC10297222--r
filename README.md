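# odinar

Observation-driven random-coefficient INAR(1) models for count time
series, built on the Poisson thinning operator.

## Why

Integer-valued series — infection counts, daily downloads, hospital
admissions — often show bursts and extreme values that classical INAR
models with binomial thinning cannot produce: a binomial survivor can
excite at most one offspring, and a constant coefficient cannot react to
the level of the process. This package implements the model

    Y_t = phi_t ⊖ Y_{t-1} + Z_t,        phi_t ⊖ y | phi_t ~ Poisson(phi_t · y)

where the thinning intensity is observation-driven through a logistic
link, A_t = E(phi_t | Y_{t-1}) = logistic(beta0 + beta1 · Y_{t-1}), and,
given the past, phi_t is either fixed at A_t or random — uniform(0, 2A_t),
exponential(mean A_t) or chi-square(df A_t). Random intensities can
transiently exceed 1, generating locally explosive stretches while the
chain stays ergodic (for the linear link this needs beta1 ≤ 0). The
innovations Z_t are iid Poisson or geometric with mean lambda.

For whom: statisticians and epidemiological modellers who need to fit,
test and simulate count autoregressions whose dependence strength itself
depends on the last count.

## What it provides

* `odinar_simulate()` — seeded trajectories from any model variant.
* `odinar(y, method = "cls" | "cml")` — conditional least squares
  (robust: only the conditional mean A_t·Y_{t-1} + lambda must be right)
  or conditional maximum likelihood under the four intensity families,
  returning a standard model object (`summary`, `coef`, `vcov`,
  `predict`, `residuals`, `simulate`, `AIC`/`BIC` for CML).
* `confidence_region_test()` / `h_statistic()` — chi-square interval
  estimation from the CLS estimating equations, no optimisation needed.
* `el_profile_test()` — profile empirical-likelihood tests of arbitrary
  parameter restrictions (e.g. H0: beta1 = 0, "is the coefficient
  observation-driven at all?").
* `compare_phi_families()` — CLS plus CML under each family with AIC/BIC,
  flagging the minimum-BIC specification.
* `run_estimation_study()`, `run_coverage_study()`,
  `run_el_power_study()` — the Monte-Carlo harness behind the numbers
  below.
* `inst/cli/odinar.R` — a thin command-line front end:
  `Rscript inst/cli/odinar.R simulate|fit|test|study ...`.

## Worked example

```r
library(odinar)

theta <- c(1, -0.6, 1.2)                   # beta0, beta1, lambda
y <- odinar_simulate(theta, odinar_spec("chisquare"), n = 1500, seed = 31)

fit <- odinar(y, method = "cls")
summary(fit)
#> Observation-driven INAR(1) fit by CLS, T = 1500 (1499 transitions)
#>         Estimate Std. Error z value  Pr(>|z|)    
#> beta0   1.687935   0.529727  3.1864   0.00144 ** 
#> beta1  -0.879484   0.168726 -5.2125 1.863e-07 ***
#> lambda  1.195250   0.062649 19.0784 < 2.2e-16 ***
#> residual sum of squares 5760.784

compare_phi_families(y, families = c("fixed", "chisquare"))
#> Coefficient-family comparison (CLS + CML fits)
#>          model  beta0   beta1 lambda      AIC      BIC converged
#>            CLS 1.6879 -0.8795 1.1953       NA       NA      TRUE
#>      cml_fixed 1.6914 -0.8840 1.1979 5591.399 5607.339      TRUE
#>  cml_chisquare 1.2067 -0.6436 1.1768 5148.376 5164.315      TRUE
#> minimum-BIC model: cml_chisquare

el_profile_test(y, restricted_idx = 2, restricted_values = 0)
#> profile empirical-likelihood test
#>   statistic = 27.9352 on 1 df (critical 3.8415, level 0.05)
#>   p-value   = 1.254e-07 -> reject
```

The chi-square intensity family that generated the data beats the
fixed-intensity fit by more than 400 BIC points; the CML fit under the
correct family pulls the slope and intercept back toward the truth
(beta0 = 1, beta1 = -0.6) where the mean-only CLS criterion, faced with
heavy-tailed intensity noise at T = 1500, overshoots them; lambda is
recovered well by both. The empirical-likelihood test firmly rejects
"the coefficient is not observation-driven" (beta1 = 0).

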