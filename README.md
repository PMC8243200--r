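# glfsr

Monte-Carlo machinery for **generalized linear factor score regression
(GLFSR)** — the two-step workflow in which a confirmatory factor model is
estimated first, factor scores are computed from it, and an observed
outcome is then regressed on those scores with an identity, logit or log
link. Factor scores are indeterminate, so the second-step coefficient
estimates and standard errors are biased in ways that depend on the
scoring method, the measurement design and the outcome family. `glfsr`
quantifies those biases by simulation for researchers in psychometrics,
biostatistics and epidemiology who use scale scores as regression
covariates.

## What it implements

* **Measurement-model simulator** — a standardized two-factor,
  eight-indicator simple-structure model `x = Λ F + δ` with
  `Θ = I − diag[ΛΦΛ′]` and `Σ = ΛΦΛ′ + Θ`; loadings drawn per replication
  from a uniform with mean `μλ ∈ {0.40, 0.60, 0.80}` and SD
  `σλ ∈ {0, 0.03, 0.09}` (endpoints `μλ ± √3·σλ`, support inside
  `[0.244, 0.956]`), interfactor correlation
  `ϕ12 ∈ {0, ±0.3, ±0.5, ±0.8}`, `n ∈ {50, …, 1000}`.
* **ULS estimation** of the free parameters (8 loadings + `ϕ12`) on the
  sample correlation matrix, with admissibility screening (non-PD
  matrices, `|ϕ̂12| > 1`, Heywood cases, optimizer failure → a
  nonconvergent replication).
* **Four scoring methods** — regression `ΦΛ′Σ⁻¹x`,
  correlation-preserving `Φ^½[Φ^½Λ′Σ⁻¹ΛΦ^½]^(−½)Φ^½Λ′Σ⁻¹x`
  (Anderson–Rubin when `Φ = I`), total sum (signed unit weights) and
  weighted sum (`Λ′x`) — plus the validity coefficient
  `ρ = diag[ΦΛ′Σ⁻¹ΛΦ]^½`.
* **Intercept-free GLM fitter** (`g(μy) = F̂γ*`) by Fisher scoring with
  the expected information, for Normal(·, 10)/identity,
  Bernoulli/logit and Poisson/log outcomes generated from the *true*
  scores with `γ = (1, 2)`; two-sided test of `H0: γ1* = 1`.
* **Performance criteria** per condition after 0.5%-per-tail trimming:
  nonconvergence rate, relative bias (RB), relative SE bias (RSEB), RMSE,
  empirical Type I error rate (α̂).
* **Meta-analysis** — Type III ANOVA (sum-to-zero contrasts, first-order
  interactions) of criteria on the design factors, partial omega-squared
  `ω̂p² = df(MSSeff − MSSerr) / (df·MSSeff + (N − df)·MSSerr)` with
  bootstrap percentile CIs and the `ω̂p² > 0.14` large-effect rule.

## Worked example

A small corner of the design — two loading levels, two interfactor
correlations, two sample sizes, identity link, 200 replications:

```r
library(glfsr)

grid <- enumerateGrid(mu_lambda = c(0.4, 0.8), sigma_lambda = 0.03,
                      phi12 = c(0, 0.5), n = c(100, 500),
                      method = c("regression", "total"), link = "identity",
                      reps = 200)
run  <- runStudy(grid, master_seed = 42)
summ <- summarizeRun(run)
summ[summ$method == "regression",
     c("mu_lambda", "phi12", "n", "nonconv", "RB", "RSEB", "RMSE", "alpha")]
#>    mu_lambda phi12   n nonconv      RB   RSEB  RMSE alpha
#> 1        0.4   0.0 100    15.5  -8.805 -42.09 0.991  8.38
#> 3        0.4   0.0 500     0.0  -5.047  -6.36 0.264  6.57
#> 5        0.4   0.5 100    10.0 -11.108 -21.16 1.347  6.18
#> 7        0.4   0.5 500     0.0  -4.238  -8.96 0.389  6.57
#> 9        0.8   0.0 100     0.0  -5.779  -5.28 0.369  5.56
#> 11       0.8   0.0 500     0.0  -1.294   2.25 0.153  3.54
#> 13       0.8   0.5 100     0.0   2.278  13.71 0.364  1.52
#> 15       0.8   0.5 500     0.0   0.688   1.44 0.184  4.55
```

Read: with weak indicators (`μλ = 0.4`) and `n = 100`, 10–16% of
replications fail measurement estimation, the regression-method
coefficient is biased downward by ~9–11% and its standard error
underestimates the sampling spread badly; with strong indicators and
`n = 500` bias is under 2% and rejection rates sit near the nominal 5%.
Factor determinacy drives all of this — e.g.

```r
validityRho(buildModel(matrix(c(rep(0.6, 4), rep(0, 8), rep(0.6, 4)), 8, 2), 0.5))
#> [1] 0.843 0.843
```

`metaAnalyze(summ, "RB")` then decomposes any criterion over the design
factors with `ω̂p²` effect sizes, and the same pipeline is scriptable from
a shell via `inst/cli/glfsr-sim` with a flat `key = value` config file.

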