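# dlnratio

Interval estimation for the **ratio of means of two delta-lognormal
populations from left-censored data**.

Rainfall, contaminant concentrations and similar environmental series
mix exact zeros with skewed positive values, and small positives below
a detection threshold ξ are only recorded as "≤ ξ". The
delta-lognormal model handles the mixture — zero with probability δ,
otherwise `log X ~ N(μ, σ²)` — and comparisons between two sites
naturally use the ratio of positive-part means

```
θ = θ₁ / θ₂,   θ_g = exp(μ_g + σ_g² / 2).
```

The package is for statisticians and environmental/hydrological
analysts who need a point estimate and a two-sided 100(1−α)% interval
for θ when both samples are left-censored.

## What it implements

* **Censored-normal fit** on the log scale: observations are split at
  ξ (zeros, ties and — by default — missing records are censored),
  and (μ, σ²) are estimated by the classical correction form
  `μ̂ = ȳ − ψ(h, a)(ȳ − log ξ)`, `σ̂² = s² + ψ(h, a)(ȳ − log ξ)²`
  with ψ built from the normal Mills ratio; one-step plug-in,
  self-consistent fixed-point, and direct likelihood maximization
  modes are provided and cross-checked against each other.
* **Four interval constructions** for θ₁/θ₂:
  generalized pivotal quantities (GCI), a conjugate Bayesian
  highest-posterior-density interval, a parametric-bootstrap normal
  approximation, and the closed-form method of variance estimates
  recovery (MOVER).
* **A Monte-Carlo engine** (`runScenario()`, `table2Grid()`)
  estimating coverage probability and average length of the four
  intervals over a 9-run × 7-sample-size scenario grid.
* **A worked application**: a bundled 30-day two-province daily
  rainfall series (Chiang Rai / Chiang Mai, June 2022, with missing
  markers preserved), AIC-based selection of the positive-part
  distribution, and an end-to-end report.

## Worked example

```r
library(dlnratio)
print(runEmpiricalExample(seed = 1))
```

```
Two-province rainfall example (censoring thresholds 0.1 / 0.1 mm)

  chiang_rai   n = 30, censored n(1) = 18, retained n(2) = 12, positives 43.33%
  chiang_mai   n = 30, censored n(1) = 23, retained n(2) = 7, positives 30.00%

  chiang_rai   mu_hat = -1.1999, sigma2_hat = 9.7111, theta_hat = 38.69
  chiang_mai   mu_hat = -1.5956, sigma2_hat = 13.3624, theta_hat = 161.67

  ratio of means theta_hat = 0.2393

  95% intervals for the ratio:
    GCI    [    0.0000,   382.0021]  length   382.0021
    BAYES  [    0.0000,   595.6788]  length   595.6788
    PB     [-12664.8652, 13333.1235]  length 25997.9887
    MOVER  [    0.0000, 20201.3372]  length 20201.3372
```

Reading the output: 18 of 30 Chiang Rai days are in the censored class
(15 dry days, one 0.1 mm trace tie, 2 unrecorded days), 12 are
retained. The fits say Chiang Rai's average positive-part rainfall is
about 0.24× Chiang Mai's, but with 12 and 7 retained observations and
log-scale variances near 10, every interval is wide — the GCI is the
tightest here, and the MOVER interval is in its flagged breakdown
regime (upper component limits exceed twice the point estimates), so
its enormous upper limit means "the ratio is essentially unbounded
above on these data". The AIC table (`aicTable()`) selects the
lognormal for both provinces (73.64 and 51.49, against 107.26 / 76.52
for the normal), supporting the model choice.

Single intervals on your own data:

```r
g <- readTwoGroupCsv("data.csv")       # wide or long CSV, "-" = missing
ciRatio(g[[1]], g[[2]], xi1 = 0.1, xi2 = 0.1, method = "bayes", seed = 7)
```

A thin command-line wrapper with the same functionality is installed
as `exec/dlratio` (`ci`, `aic`, `example`, `simulate` subcommands).

## Coverage simulations

```r
cfg <- scenarioConfig(run = 1, n1 = 30, n2 = 30, M = 5000, m = 2500, seed = 2)
runScenario(cfg, methods = "bayes")
#> coverage 0.9820, average length 2.3639
```

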