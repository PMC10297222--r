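---
title: "Observation-driven random-coefficient INAR(1): model, estimators and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Observation-driven random-coefficient INAR(1): model, estimators and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odinar)
```

## The model

A count series $Y_1, \dots, Y_T$ follows the observation-driven INAR(1)
recursion built on the Poisson thinning operator,

$$Y_t = \phi_t \ominus Y_{t-1} + Z_t,
\qquad \phi_t \ominus Y_{t-1} \mid \phi_t, Y_{t-1}
\sim \mathrm{Poisson}(\phi_t Y_{t-1}),$$

where the thinning operator replaces the scalar multiplication of a
Gaussian AR(1): each of the $Y_{t-1}$ units present at $t-1$ spawns an
independent Poisson$(\phi_t)$ number of units at $t$ (so one unit can
excite several — the one-to-many channel that binomial thinning cannot
express), and $Z_t$ are iid non-negative innovations with mean $\lambda$
(Poisson or geometric here). The thinning intensity is driven by the
previous observation through a logistic link,

$$A_t = E(\phi_t \mid Y_{t-1})
= \frac{\exp[\nu(Y_{t-1}; \beta)]}{1 + \exp[\nu(Y_{t-1}; \beta)]},
\qquad \nu(y; \beta) = \beta_0 + \beta_1 y \ \text{(default link)},$$

and, given $Y_{t-1}$, $\phi_t$ may be *fixed* at $A_t$ or drawn from a
*uniform* $(0, 2A_t)$, *exponential* (mean $A_t$) or *chi-square* (df
$A_t$) distribution. The random families occasionally push $\phi_t$ above
1, producing locally explosive bursts — the extreme values typical of
epidemic counts — without destroying overall ergodicity. With the linear
link, stability demands $\beta_1 \le 0$ (intensity decreasing in the
level); `stationarity_check()` warns, and the simulator forwards the
warning, when $\beta_1 > 0$.

Conditional moments used throughout:
$E(Y_t \mid Y_{t-1}) = A_t Y_{t-1} + \lambda$ and, by total variance,
$\mathrm{Var}(Y_t \mid Y_{t-1}) = A_t Y_{t-1} + Y_{t-1}^2
\mathrm{Var}(\phi_t \mid Y_{t-1}) + \sigma^2_Z$. We use the
total-variance form (with the $Y_{t-1}^2$ factor) rather than the
shorter expression sometimes quoted without it; no estimator in the
package depends on the conditional variance, so the choice is
diagnostic-only.

## Mixture transition probabilities

Conditional on $Y_{t-1} = y > 0$, the thinned component is a Poisson
mixture over the $\phi$-distribution, with closed forms (`thinning_pmf()`):

* fixed: $\mathrm{Poisson}(A y)$ at $k$;
* uniform$(0, 2A)$: $\gamma(k + 1,\, 2Ay) / (2Ay\, k!)$ — note the
  incomplete-gamma argument is $2Ay$, as direct integration requires
  (a variant with argument $2A$ circulates but is not a probability
  distribution; every closed form here is tested against adaptive
  quadrature of the mixture integral at $10^{-8}$);
* exponential with mean $A$: $(Ay)^k / (Ay + 1)^{k+1}$. A published
  closed form corresponds instead to an exponential with *rate* $A$
  (mean $1/A$), contradicting the stated conditional mean; we default to
  the mean-$A$ convention (`exp_convention = "mean"`, consistent with the
  logistic conditional expectation) and expose the rate-$A$ form as
  `exp_convention = "rate"`. Simulator and likelihood always share the
  chosen convention, so parameter recovery is self-consistent either way;
* chi-square with df $A$ (gamma shape $A/2$, scale 2, non-integer df
  allowed): $\frac{y^k}{k!}\, 2^{-A/2}\,
  \frac{\Gamma(k + A/2)}{\Gamma(A/2)\, (y + 1/2)^{k + A/2}}$ — the
  normaliser is $2^{A/2}$, the standard chi-square constant.

The one-step transition probability convolves the thinning mixture with
the innovation pmf; all pmf arithmetic is in log space (`lgamma`,
log-sum-exp) since counts in the dozens overflow naive factorials.

## Estimators

**Conditional least squares (CLS).** Minimises $S(\theta) = \sum_{t\ge2}
(Y_t - A_t Y_{t-1} - \lambda)^2$. Because $\lambda$ enters linearly it is
profiled out in closed form (mean of the partial residuals), and the
two-dimensional $\beta$ criterion is minimised by BFGS with analytic
gradients from five deterministic starts ($\beta = 0$ and four unit
perturbations); short bursty series can make the criterion multimodal.
CLS only requires the conditional mean to be right, so it is robust to
the $\phi$-family and to innovation misspecification. Its asymptotic
covariance is the sandwich $V^{-1} W V^{-1}$ with $W$ the mean outer
product of the estimating functions $M_t$ and $V$ the mean curvature of
the regression function, both averaged over the $T - 1$ usable
transitions; standard errors are $\sqrt{\mathrm{diag}(V^{-1}WV^{-1})/T}$.
The curvature keeps the full sample analogue including the
second-derivative term, although that term has mean zero at the truth.

**Interval estimation.** $H(\theta) = (\sum_t M_t)' (\sum_t M_t
M_t')^{-1} (\sum_t M_t)$ is asymptotically $\chi^2_{\ell+1}$ at the true
parameter (outer-product matrix uncentred, sums over $t = 2..T$), giving
confidence regions $\{\theta : H(\theta) \le C_\alpha\}$ with
$P(\chi^2_{\ell+1} \le C_\alpha) = \alpha$ — no optimisation, one $O(T)$
pass per evaluation. $H$ is exactly 0 at the CLS estimate
(just-identified estimating equations).

**Conditional maximum likelihood (CML).** Minimises $-\sum_{t\ge2} \log
P(Y_t \mid Y_{t-1})$; the marginal of $Y_1$ is unknown and ignored.
Bounded quasi-Newton (`L-BFGS-B`, $\lambda \ge 10^{-6}$) warm-started at
the CLS fit, with two fallback starts used only if the warm start fails.
The covariance is the inverse Fisher information estimated by the mean
outer product of per-transition scores (finite differences, relative step
$10^{-5}$); tests cross-check it against the observed Hessian within
10%. CML is more efficient than CLS under a correct specification and
visibly biased under a wrong one (e.g. geometric innovations fitted with
a Poisson likelihood bias $\hat\lambda$ downward) — the classic
robustness/efficiency trade-off the estimation studies quantify.

**Empirical likelihood (EL).** Weights $p_t$ on the transitions maximise
$\prod T' p_t$ subject to $\sum p_t M_t(\theta) = 0$; the inner Lagrange
problem is solved by damped Newton on Owen's log-star extension
(threshold $1/T'$, quadratic continuation below it keeps the objective
twice differentiable while enforcing positivity in the limit), residual
tolerance $10^{-11}$. A genuine interior solution also has $\sum p_t =
1$; when the origin falls outside the convex hull of the $M_t$ the
residual can vanish along a runaway direction with $\sum p_t < 1$, which
we detect and report as a hull violation ($\mathcal{L}_E = \infty$, i.e.
"this $\theta$ is incompatible"). Because the system is just-identified,
the EL point estimate *is* the CLS estimate and $\mathcal{L}_E$ is zero
there, so the profile test statistic for a restriction needs no
subtraction.

One deliberate deviation from a printed account of this test: the
statistic we compare to $\chi^2_q$ is the Wilks ratio $-2\log\mathcal{R}
= 2 \min \mathcal{L}_E$, with the conventional factor 2 of the
empirical-likelihood literature. A version of the theorem circulates
stating $\mathcal{L}_E$ itself is $\chi^2_q$; simulating the null at $T
= 2000$ shows $\min\mathcal{L}_E$ has mean $\approx 0.50$ while $2
\min\mathcal{L}_E$ matches $\chi^2_1$ closely (and only the factor-2
version reproduces a Type-I error that converges to the nominal level),
so the factor 2 is what the reference simulations must have used.
Nuisance components are minimised out by Nelder-Mead (tolerance
$10^{-7}$, 500 iterations; `optimize` when only one component is free)
warm-started at the restricted CLS fit — $\mathcal{L}_E$ is only
piecewise-smooth in $\theta$ through $\gamma(\theta)$, so a
derivative-free method is safer than quasi-Newton. Arbitrary restricted
index sets are supported, not just leading blocks. When the intensity is
genuinely random given the past, the EL test's Type-I error inflates
badly (the estimating equations only encode the linear mean structure);
the CLI therefore refuses `test` under a stochastic family unless
`--force-el` is passed.

## The simulator as a stated world

`odinar_simulate()` draws $\phi_t$ from the chosen family, then the
thinned component as one Poisson$(\phi_t Y_{t-1})$ draw — exactly
equivalent in distribution to summing $Y_{t-1}$ iid Poisson$(\phi_t)$
variables, but $O(1)$ per step — then adds the innovation. The reference
design nowhere states an initial value or burn-in; we start at $y_0 = 0$
and discard 500 steps, which is far beyond the chain's geometric mixing
time at the study parameters ($\beta_0 = 1$, $\beta_1 = -0.6$, $\lambda =
1.2$), so initialisation noise is negligible at $T \ge 300$. Studies give
replicate $r$ the seed `base_seed + r`, making every cell reproducible
and independent of execution order. What the generator does *not*
emulate: real epidemic series have covariates, seasonality and reporting
artefacts; a green Monte-Carlo table establishes correctness of the
estimators under the model, not adequacy of the model for any particular
data set.

## Numerical choices and degenerate inputs

* Logistic evaluated on a sign-split branch; no overflow for $|\nu| \le
  700$.
* Infinite sums (normalisation, moments) truncated when the tail bound
  drops below $10^{-12}$.
* An all-zero series makes CLS degenerate (every $A_t$ fits equally
  well); this is an explicit error, not a silent answer.
* Optimiser failures surface as `converged = FALSE` on the fit object,
  never as an exception mid-study; study cells report the exclusion
  count and warn if it exceeds 1%.
* AIC$= 2\,\mathrm{negLL} + 2k$, BIC$= 2\,\mathrm{negLL} + k\log T$ with
  $T$ the full series length: the reference model-comparison table has
  BIC − AIC $= 10.762 = 3(\log 267 - 2)$ in every column, which pins the
  $n = T$ convention.

## Known limitations

Single series, first-order dependence, linear link as the tested default;
no forecasting beyond the one-step conditional mean exposed via
`predict()`; EL confidence regions by statistic inversion are not
provided (the $H(\theta)$ regions serve that purpose); the geometric
innovation family is supported in the simulator and likelihood plumbing
chiefly for misspecification studies.
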