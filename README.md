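# spatlogit

Bayesian random-parameters spatial logistic regression for crash fatality
risk on segmented roadways.

## What it is for

Road-safety and injury-epidemiology analyses often need to quantify how a
post-crash factor — above all emergency medical service (EMS) response time —
changes the odds that a crash is fatal, from crash-level records located
along a freeway. Two features of such data break a plain logistic
regression: severities of crashes on nearby roadway sections are correlated
through shared unobserved conditions, and some covariate effects (e.g. truck
involvement) vary across crashes. `spatlogit` fits the nested ladder of
models that addresses both, by Metropolis-within-Gibbs MCMC with diffuse
priors:

| family | linear predictor |
|---|---|
| `logistic` | β₀ + Σⱼ βⱼ xᵢⱼ |
| `spatial` | β₀ + Σⱼ βⱼ xᵢⱼ + φ_m(i) |
| `rp_spatial` | β₀ + Σⱼ β(i)ⱼ xᵢⱼ + φ_m(i) |

The section effects φ follow a Leroux conditional autoregressive (CAR) prior
on first-order adjacency,

φ_m | φ₋ₘ ~ N( ρ Σₙ ω_mn φₙ / (1 − ρ + ρ Σₙ ω_mn),
δ² / (1 − ρ + ρ Σₙ ω_mn) ),

with ρ ∈ [0,1] interpolating between independence and the intrinsic CAR, and
random parameters follow β(i)ⱼ = β̄ⱼ + μᵢⱼ, μᵢⱼ ~ N(0, σⱼ²). Priors:
N(0, 10⁴) on coefficients, U(0,1) on ρ, U(0.01, 10) on δ and σⱼ. Effects are
reported as odds ratios exp(β), percent odds changes 100(exp(β) − 1),
average marginal effects on the fatality probability, the share
Φ(β̄ⱼ/σⱼ) of crashes with a positive random coefficient, and models are
compared by DIC = D̄ + p_D with a strict ΔDIC > 10 superiority rule.

The package also ships a synthetic-data generator with recorded truth
(covariate marginals, a section chain, exact joint CAR draws, heterogeneous
coefficients, Bernoulli outcomes), roadway segmentation and adjacency
utilities, strict CSV I/O, and convergence diagnostics. See the methods
vignette (`vignettes/spatlogit-methods.Rmd`) for the full model account,
design choices and limitations.

## Worked example

Simulate a full-size study (1,414 crashes on a 154-section chain, known
truth: EMS 0.026/min, truck mean 0.51 with SD 1.23, ρ = 0.68, δ = 0.56) and
fit the random-parameters spatial model:

```r
library(spatlogit)

sim <- simulate_crash_data(n = 1414, m = 154, seed = 42)
fit <- spatlogit(
  fatal ~ ems_time + truck + other_vehicle + non_local_vehicle + curvature +
    grade + afternoon + rear_end_crash + angle_crash + precipitation,
  data = sim$data, network = sim$network,
  family = "rp_spatial", random = "truck",
  control = mcmc_control(n_iter = 20000, n_burnin = 10000), seed = 42)
summary(fit)
```

```
Bayesian random-parameters spatial logistic model
1414 crashes (95 fatal)

 parameter         mean (SD)        95% CI             MC ratio
 (Intercept)       -8.45 (1.03)**   [-10.7, -6.55]     0.096
 ems_time          0.0189 (0.0105)* [-0.00322, 0.0389] 0.047
 truck             0.708 (0.581)    [-0.655, 1.68]     0.067
 ...
 sd_truck          1.1 (0.746)**    [0.048, 2.75]      0.077
 rho               0.605 (0.297)**  [0.0336, 0.982]    0.109
 delta             0.631 (0.343)**  [0.0509, 1.37]     0.067
---
* significant at 90%, ** at 95% credibility (interval excludes 0)

Random coefficients:
  truck: mean 0.708, SD 1.1 -> 73.9% of crashes with a positive effect

Dbar = 276.1, pD = 40.1, DIC = 316.2
```

The generative values sit inside every interval: the EMS effect (truth
0.026) is estimated at 0.019 ± 0.011, the truck heterogeneity SD (truth
1.23) at 1.1, ρ (truth 0.68) at 0.61, δ (truth 0.56) at 0.63. Stars mark
credible intervals excluding zero; the MC ratio column is the
Monte-Carlo-error convergence diagnostic (pass < 0.05 — run longer chains,
as in the 100,000-iteration default, to drive all parameters under it).

Effect sizes in the reporting conventions:

```r
odds_ratio(coef(fit)["ems_time"])
#>            estimate odds_ratio percent_change
#> ems_time 0.01887404   1.019053       1.905328
average_marginal_effect(fit, "ems_time", delta = 10)
#> [1] 0.004190794          # +10 min EMS -> ~0.42 more fatal crashes per 100
```

Comparing the ladder on the same data:

```r
compare_models(logistic = plain, spatial = spat, rp_spatial = fit)
#>        model     dbar       pd      dic delta_dic considerably_superior_to_next
#> 1 rp_spatial 276.0837 40.09695 316.1807 0.0000000                         FALSE
#> 2    spatial 288.9320 27.49907 316.4311 0.2504102                         FALSE
#> 3   logistic 307.9162 10.97757 318.8938 2.7131542                            NA
```

(at this single seed and chain length the three DICs are within 3 points:
no family is "considerably superior", which requires ΔDIC > 10).

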