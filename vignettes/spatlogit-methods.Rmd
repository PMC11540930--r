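---
title: "Models and methods in spatlogit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in spatlogit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Whether a roadway crash kills someone depends on what happened in the crash
(vehicles involved, collision type, geometry, weather) and on what happens
afterwards — above all how quickly emergency medical services (EMS) reach the
scene. `spatlogit` fits Bayesian logistic models for a binary fatality
outcome on crashes located along a segmented roadway, designed for the
epidemiological question "how much does each extra minute of EMS response
time raise the odds of death?" while accounting for two nuisances that bias
naive logistic fits:

* **spatial correlation** — crashes on nearby roadway sections share
  unobserved conditions (lighting, enforcement, pavement), inducing
  dependence between their severities;
* **unobserved heterogeneity** — a covariate's effect (e.g. truck
  involvement) can differ across crashes in ways the recorded covariates
  cannot explain.

# The model ladder

For crash $i$ with covariates $x_{ij}$ in section $m(i)$, all three families
model $Y_i \sim \mathrm{Bernoulli}(p_i)$ with

$$\operatorname{logit} p_i \;=\; \beta_0 + \sum_j \beta_{(i)j} x_{ij} + \varphi_{m(i)}.$$

1. **`logistic`** — fixed coefficients, no section term
   ($\varphi \equiv 0$). Equivalent to the latent-utility formulation in
   which $Y_i = 1$ exactly when $U_i = \beta_0 + \sum_j \beta_j x_{ij} +
   \varepsilon_i > 0$ with standard-logistic $\varepsilon_i$; estimation uses
   the Bernoulli likelihood directly.
2. **`spatial`** — adds section effects $\varphi_m$ with a Leroux
   conditional autoregressive (CAR) prior on the first-order adjacency graph
   ($\omega_{mn} = 1$ when sections share an end):
   $$\varphi_m \mid \varphi_{-m} \sim N\!\left(
     \frac{\rho \sum_n \omega_{mn}\varphi_n}{1-\rho+\rho\sum_n \omega_{mn}},\;
     \frac{\delta^2}{1-\rho+\rho\sum_n \omega_{mn}}\right).$$
   $\rho \in [0,1]$ interpolates between independent effects ($\rho = 0$)
   and the intrinsic CAR ($\rho = 1$); $\delta$ sets the conditional scale.
   For $\rho < 1$ the joint is a proper normal with precision
   $Q = \{\rho(D - W) + (1-\rho)I\}/\delta^2$, where $W$ is the adjacency
   and $D$ its row sums.
3. **`rp_spatial`** — additionally gives selected coefficients crash-level
   random parameters $\beta_{ij} = \bar\beta_j + \mu_{ij}$,
   $\mu_{ij} \sim N(0, \sigma_j^2)$, so e.g. a truck's presence can raise
   fatality odds in some crashes and lower them in others; the share with a
   positive effect is $\Phi(\bar\beta_j/\sigma_j)$.

Priors are deliberately diffuse: $N(0, 10^4)$ (variance parameterization) on
$\beta_j$ and $\bar\beta_j$, $U(0,1)$ on $\rho$, and $U(0.01, 10)$ on
$\delta$ and every $\sigma_j$.

Random parameters are attached at the crash level, exactly as the
formulation states, even though a unit-level random coefficient observed
through a single binary outcome is weakly identified; identification rests
on the normal mixing prior. The consequences are discussed under
*Limitations*.

# Estimation

`spatlogit()` runs one chain of adaptive Metropolis-within-Gibbs (default
100,000 iterations, 50,000 burn-in, no thinning — configurable via
`mcmc_control()`):

* coefficients and random-coefficient means: per-parameter random walks,
  with proposal scales adapted toward 44% acceptance during burn-in only
  (diminishing adaptation);
* crash-level deviations $\mu_{ij}$: a 50/50 mixture of a random walk and an
  independence proposal from the mixing prior $N(0, \sigma_j^2)$ — the
  independence kernel keeps the deviations' feedback on $\sigma_j$ sharp
  where the per-crash likelihood is nearly flat;
* section effects $\varphi_m$: single-site Metropolis with the exact Leroux
  full conditional as prior plus the section's likelihood contribution
  (sections with no crashes therefore receive prior-only updates);
* $\rho$: random walk on the logit scale with Jacobian, using the joint CAR
  density via the precomputed eigenvalues of $D - W$; $\rho = 1$ is handled
  only conditionally (the joint is improper there, and the $U(0,1)$ prior
  makes the boundary measure-zero);
* $\delta$, $\sigma_j$: random walks on the log scale truncated to the prior
  support, repeated three times per sweep, *plus* joint rescaling moves
  $(\sigma_j, \mu_{\cdot j}) \to (e^\epsilon \sigma_j, e^\epsilon
  \mu_{\cdot j})$ and $(\delta, \varphi) \to (e^\epsilon \delta, e^\epsilon
  \varphi)$ whose prior terms cancel, leaving a likelihood-ratio
  acceptance. Scale parameters are the slow directions of the hierarchy and
  get the extra work.

Coefficients start at the maximum-likelihood logistic estimates
(`glm.fit`), the convention of areal-model packages: at ~2–7% event rates a
zero start produces transients of tens of thousands of iterations.
`init = list(beta = 0)` restores a zero start; section effects start at 0,
$\rho$ at 0.5, $\delta$ and $\sigma$ at 1. `prior_only = TRUE` switches the
likelihood off, which is how the test suite verifies that each prior is
recovered exactly.

Convergence is monitored by the Monte-Carlo-error rule: a parameter passes
when its batch-means MC error (50 batches) is strictly below 5% of its
posterior SD (`convergence_check()`); trace ("history") plots come from
`plot()`. The companion decision rule for a random coefficient — collapse it
back to fixed when its posterior spread shows no detectable heterogeneity —
is operationalized as "the 2.5th posterior percentile of $\sigma_j$ falls
below twice the lower prior bound (0.02)", since an interval for a
positive-support parameter can never bracket zero. The threshold is
configurable in `classify_random_parameter()`.

# Reporting

`summary()` gives posterior means, SDs, 90/95% equal-tailed credible
intervals with significance flags (interval excludes 0), MC-error ratios,
odds ratios $e^{\beta}$ and percent changes $100(e^{\beta}-1)$.
`average_marginal_effect()` computes the mean change in fatality probability
for a `delta`-unit covariate increase, averaged over crashes and (by
default) over posterior coefficient draws, with section effects and
crash-level deviations entering at their posterior means; `method =
"plugin"` evaluates everything at posterior means, and `ame_profile()` gives
the same quantity at user-supplied (e.g. generative) coefficients.

Model comparison uses the conditional DIC: $\bar D$ is the posterior mean of
$-2\log L$ evaluated at the sampled $\varphi$ and $\beta_{ij}$ (the
WinBUGS-style focus), $p_D = \bar D - D(\hat\theta)$ with $D(\hat\theta)$ at
the posterior means of all focus parameters, and $\mathrm{DIC} = \bar D +
p_D$. `compare_models()` ranks fits and flags one model "considerably
superior" to another only when its DIC is lower by strictly more than 10.
A marginal DIC is out of scope.

# The synthetic-data generator

Because crash-level data of this kind are rarely shareable, the package
ships a generator (`simulate_crash_data()`) reproducing the statistical
structure the models assume, with recorded truth for recovery studies:

* **Covariates** (`generate_covariates()`): indicator groups (vehicle type,
  time of day, crash type) are drawn categorically so they are genuinely
  one-hot with all-zero reference rows (passenger car, before dawn,
  single-vehicle); since the published shares are "at least one ..." flags
  that overlap, the reference probability absorbs the overlap and the
  non-reference shares are matched exactly. EMS response time uses a
  truncated log-normal matched to mean 19.56 / SD 16.61 minutes on
  [1, 260] — a positively skewed family is the natural choice for a
  response-time distribution, and only its first two moments and range are
  published. Other continuous covariates use truncated normals (or
  log-normals when the SD rivals the mean); hourly precipitation is a
  wet/dry mixture (15% wet) with a moment-matched log-normal wet amount.
  Covariates are generated independently, consistent with the reported
  absence of correlation and collinearity.
* **Sections**: a 154-section chain by default; crashes are assigned to
  sections uniformly at random (per-section crash counts are not published);
  a custom assignment can be passed to `generate_outcomes()`.
* **Spatial effects** (`generate_spatial_effects()`): one exact joint draw
  from the Leroux normal via the Cholesky factor of $Q$ ($\rho = 0.68$,
  $\delta = 0.56$ by default); $\rho = 1$ is rejected for generation.
* **Outcomes** (`generate_outcomes()`): $\mu_{ij}$ drawn from the mixing
  law ($\sigma_{\mathrm{truck}} = 1.23$), the linear predictor assembled,
  and $Y_i$ drawn Bernoulli. The recorded truth reproduces every crash's
  generative probability exactly.

The default coefficient truth is the full random-parameters column of the
reference fit (intercept $-7.10$, EMS $0.026$/min, truck mean $0.51$, ...,
precipitation $0.95$/mm). One inconsistency in those published values
matters for generation: a precipitation coefficient of $0.95$ per mm
together with precipitation moments of mean 0.76 / SD 3.425 / max 54.8 mm
forces a generative fatality rate of 6–7% under independent marginals — the
mean alone implies the average crash's odds are at least doubled, and the
second moment forces a few percent of crashes above 10 mm where the
probability saturates. No wet-hour distribution matching those moments can
reproduce the observed 2.5% rate at those coefficients; the real covariate
joint evidently differs from independent marginals. The generator therefore
keeps the faithful defaults (the rate lands near 7%), and
`target_rate = 0.025` re-solves the intercept with `calibrate_intercept()`
when the observed-rate regime is wanted. Tests and the acceptance script use
the default truth for recovery and model-comparison studies and the
calibrated intercept for rate-sensitive quantities (the intercept-only
check, fatality counts, the EMS marginal effect).

Passing recovery tests on these data show the estimation machinery is
correct for the assumed structure; they cannot show that real crash data
satisfy that structure (independent covariates, exactly normal mixing,
chain adjacency, pre-matched weather).

# Numerical choices

* Logistic quantities use `plogis` / a guarded `log1p(exp())` everywhere;
  the likelihood is exact for $|\eta|$ up to overflow.
* The linear predictor is maintained incrementally in the sampler and
  refreshed from scratch every 2,000 iterations against drift.
* Chain networks and edge lists are validated (symmetry, zero diagonal,
  0/1 entries, no self-edges, unique labels); geometry segmentation merges
  consecutive intervals homogeneous in curvature and grade with exact
  equality (zero tolerance) as the default criterion, and crashes map to
  sections by half-open $[{\rm start}, {\rm end})$ intervals so boundary
  assignment is unique.
* Draw storage keeps every scalar parameter; the section-effect field is
  summarized by running means/SDs plus up to `phi_keep_max` thinned joint
  draws.
* Problem sizes in the test suite: recovery runs use 10 seeded replicates
  of the full 1,414-crash / 154-section design at 20,000 iterations
  (10,000 burn-in); model-comparison runs use 10,000 iterations. These are
  the package's scaled study sizes for routine verification; the defaults
  (100,000 / 50,000) remain the recommended analysis protocol.

# Limitations

* **Weak identification of crash-level random parameters.** A per-crash
  random coefficient observed through one Bernoulli outcome is identified
  only through the mixing prior. Cross-checking against an exact
  grid-plus-quadrature posterior on a reduced intercept-plus-truck model
  (1,414 crashes, 2.5% fatality rate, no true heterogeneity) shows the
  posterior under the diffuse priors is *bimodal*: roughly half its mass
  sits in an overfitting regime ($\sigma \approx 5$–$9$ with a strongly
  negative co-adapted intercept) that the sampler reproduces faithfully
  (gold standard $E[\sigma \mid y] = 4.8$, $P(\sigma > 5) = 0.53$; sampler
  4.7 and 0.52). Two practical consequences: posterior summaries for
  $\sigma$ can be strongly prior- and regime-dependent at low event counts,
  and the collapse rule's 0.02 threshold is undetectably strict there — the
  exact posterior's 2.5th percentile on truly-null data is an order of
  magnitude above it. Users should treat retained heterogeneity as
  suggestive rather than decisive at rare-event rates.
* **Conditional DIC** rewards the same overfitting (deviance conditions on
  the sampled crash-level effects), so DIC gaps between the random-
  parameters family and simpler families should be read alongside $p_D$.
* The generator emulates marginals, not the joint covariate law; see above.
* One chain by default, as in the reference protocol; multi-chain
  diagnostics require fitting repeatedly with different seeds and
  over-dispersed `init`.
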