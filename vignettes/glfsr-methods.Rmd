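---
title: "Methods: simulating generalized linear factor score regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating generalized linear factor score regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glfsr)
```

## The problem

Factor score regression (FSR) is the common two-step workaround for
structural equation modelling: fit a confirmatory factor model to a set of
indicators, compute factor score estimates, then regress an outcome on the
scores as if they were observed covariates. Because factor scores are
indeterminate — infinitely many score sets are consistent with any fitted
measurement model — the second-step coefficients and standard errors inherit
biases that depend on the scoring method, the measurement design and the
outcome model. `glfsr` provides the machinery to quantify those biases for
*generalized linear* FSR (GLFSR), where the outcome may be normal,
Bernoulli or Poisson.

## The measurement model

The generator emulates a standardized two-factor, eight-indicator design
with simple structure: indicators 1–4 load on factor 1, indicators 5–8 on
factor 2, no cross-loadings,

$$x = \Lambda F + \delta, \qquad F \sim N_2(0, \Phi), \quad
  \delta \sim N_8(0, \Theta),$$

with $\Phi$ a correlation matrix (unit factor variances) and, because the
indicators are standardized, $\Theta = I - \mathrm{diag}[\Lambda \Phi
\Lambda']$ so that $\Sigma = \Lambda\Phi\Lambda' + \Theta$ has unit
diagonal. Every loading is then interpretable as an indicator–factor
correlation.

Loadings are drawn fresh each replication from a uniform distribution
parameterized by its mean $\mu_\lambda$ and standard deviation
$\sigma_\lambda$: the endpoints are $\mu_\lambda \pm \sqrt{3}\,
\sigma_\lambda$, the unique uniform with those two moments. Over the
design's levels ($\mu_\lambda \in \{0.40, 0.60, 0.80\}$, $\sigma_\lambda
\in \{0, 0.03, 0.09\}$) the support stays inside $[0.244, 0.956]$, so no
truncation is ever applied — draws cannot leave the valid correlation
range, and the degenerate $\sigma_\lambda = 0$ case reduces to equal
loadings. All eight loadings are i.i.d. from the condition's single
distribution.

The full design crosses $\mu_\lambda$ (3) × $\sigma_\lambda$ (3) ×
$\phi_{12} \in \{0, \pm 0.3, \pm 0.5, \pm 0.8\}$ (7) × $n \in \{50, 100,
200, 500, 1000\}$ (5) × four scoring methods × three links = 3,780
conditions, 1,000 replications each in the reference setting.

## ULS estimation and admissibility

Free parameters (eight loadings and $\phi_{12}$) are estimated by
unweighted least squares on the sample correlation matrix: minimize the sum
of squared differences between the lower off-diagonal elements of $S$ and
of $\Lambda\Phi\Lambda'$. The error variances are not free; they are derived
as $\hat\theta_{ii} = 1 - [\hat\Lambda\hat\Phi\hat\Lambda']_{ii}$, so a
Heywood case surfaces as a negative derived error variance. Numerical
choices:

* quasi-Newton minimization (`nlminb`) with an analytic gradient,
  start values 0.5 for loadings and 0 for $\phi_{12}$, at most 500
  iterations;
* $\phi_{12}$ is left unconstrained and $|\hat\phi_{12}| > 1$ is caught by
  the admissibility check afterwards, mirroring how mainstream SEM software
  reports rather than prevents such solutions;
* factor signs are aligned so each loading column sums positive (the ULS
  criterion is invariant to column sign flips; alignment makes the reported
  solution unique);
* positive definiteness is declared when the smallest eigenvalue exceeds
  1e-10.

A replication is nonconvergent when the sample correlation matrix, the
estimated factor correlation matrix, the derived error-variance matrix or
the model-implied correlation matrix fails positive definiteness, when
$|\hat\phi_{12}| > 1$, when loadings are missing, when the optimizer fails,
or when second-step coefficient or standard error estimates are missing.
Nonconvergence depends only on the measurement side, so the per-replication
RNG stream is keyed on (measurement condition, replication index, master
seed) and never on the scoring method or link — the same draws feed all
method × link cells, making nonconvergence identical across them by
construction.

## Scoring methods

With $\hat\Lambda$, $\hat\Phi$ and an estimate of $\Sigma$, the four weight
matrices are

* regression: $W = \hat\Phi \hat\Lambda' \Sigma^{-1}$ (best linear
  predictor; maximizes score–factor correlation, the validity
  $\rho = \mathrm{diag}[\Phi\Lambda'\Sigma^{-1}\Lambda\Phi]^{1/2}$);
* correlation-preserving: $W = \hat\Phi^{1/2} [\hat\Phi^{1/2} \hat\Lambda'
  \Sigma^{-1} \hat\Lambda \hat\Phi^{1/2}]^{-1/2} \hat\Phi^{1/2}
  \hat\Lambda' \Sigma^{-1}$, whose asymptotic score covariance equals
  $\hat\Phi$ (Anderson–Rubin when $\hat\Phi = I$);
* total sum: signed unit weights $(\Lambda^*)'$;
* weighted sum: $\hat\Lambda'$.

Scores are computed on columnwise-standardized data, consistent with the
correlation-metric model. Symmetric matrix square roots use an
eigendecomposition with a 1e-12 eigenvalue floor; a non-invertible inner
matrix flags the replication instead of erroring.

Which $\Sigma$ enters the regression and correlation-preserving weights is
a genuine fork: the sample correlation matrix $S$ is the natural estimator
in a correlation-metric model and is the package default; the model-implied
$\hat\Sigma = \hat\Lambda\hat\Phi\hat\Lambda' + \hat\Theta$ is available
via `sigma = "model"` (`score_sigma` in `runStudy()`). The two coincide
asymptotically but differ at finite $n$: with the model-implied matrix the
regression method's small-sample coefficient bias nearly vanishes, while
with $S$ it shows the moderate negative bias reported in the FSR
literature for unit-variance-scaled models. The sample-matrix default is
the behaviour the package's own acceptance checks replicate. At population
parameter values the choice is immaterial, which is how the exact score
identities (correlation preservation $W\Sigma W' = \Phi$, the Woodbury
form of the regression-score covariance) are tested.

## The outcome model and its fit

Outcomes are generated from the *true* factor scores with coefficients
$\gamma = (1, 2)$ and no intercept: $y \mid f \sim N(f_1 + 2 f_2, 10)$
(identity), $\mathrm{Bernoulli}(\mathrm{logit}^{-1}(f_1 + 2 f_2))$ (logit),
$\mathrm{Poisson}(e^{f_1 + 2 f_2})$ (log). The conditional variance 10 for
the normal outcome keeps the linear signal from dominating. The second
step fits $g(\mu_y) = \hat F \gamma^*$ — intercept-free, since all
variables are centered by construction — by Fisher scoring with the
expected information (for these canonical links the iteration is ordinary
IRLS). Numerical choices:

* initialization from adjusted responses, as in standard GLM fitters
  ($\eta_0 = \log(y + 0.1)$ for the log link, $\mathrm{logit}((y + 0.5)/2)$
  for the logit link). A cold start at $\gamma^* = 0$ was tried first and
  rejected: the first Poisson Fisher step can overshoot by two orders of
  magnitude and then creep back too slowly to meet any reasonable
  iteration cap;
* convergence when the relative coefficient change drops below 1e-10, at
  most 100 iterations;
* the linear predictor is clipped at ±30 inside the inverse link during
  iteration; a "solution" sitting on that boundary (the footprint of
  complete separation) is flagged nonconvergent, as are non-finite
  coefficients or standard errors;
* the Gaussian dispersion is the residual mean square on $n - 2$ degrees
  of freedom, and the identity-link test of $H_0: \gamma_1^* = 1$ uses a
  $t(n-2)$ reference; the logit and log links use Wald $z$ tests, matching
  standard GLM practice. At $n \ge 50$ the distinction moves empirical
  rejection rates by well under a point.

## Performance criteria

Per (condition, method, link) cell: the nonconvergence rate (percent of
all scheduled replications, computed before trimming), and — on the
convergent replications after discarding the $\lceil 0.005\,C\rceil$
smallest and largest $\hat\gamma_1^*$ per tail — relative bias
$\mathrm{RB} = 100\,\overline{(\hat\gamma_1 - 1)}$, relative standard
error bias $\mathrm{RSEB} = 100\,(\overline{SE} / \mathrm{SD}(\hat\gamma_1)
- 1)$ with the $C - 1$ sample SD, $\mathrm{RMSE} =
[\overline{(\hat\gamma_1 - 1)^2}]^{1/2}$, and the empirical Type I error
rate, the percentage with $p < 0.05$ (strict inequality). The ceiling rule
gives exactly 5 per tail at 1,000 replications and guarantees at least one
removal at any positive trim fraction; trimming is applied independently
per cell because $\hat\gamma_1^*$ differs per cell, and all four trimmed
criteria are computed on the same trimmed set. Untrimmed means can be
dominated by near-singular fits at weak loadings and high interfactor
correlation — single replications with relative errors of several hundred
percent — which is exactly what the trimming rule is for. Cells with fewer
than 10 convergent replications are marked unusable and excluded from
downstream analysis rather than reported.

## Meta-analysis

Condition-level criteria are related to the design factors (all treated as
unordered categoricals, including $n$ and $\phi_{12}$) by fixed-effects
ANOVA with main effects and all first-order interactions under sum-to-zero
contrasts. Type III sums of squares are computed literally: the SS of a
term is the residual-SS increase when that term's columns are deleted from
the full model. On the complete grid this yields the classical layout —
method 3 df, link 2 df, method:link 6 df, residual 3,616 df. Effect sizes
use partial omega-squared,

$$\hat\omega^2_p = \frac{df(\mathit{MSS}_{\mathrm{eff}} -
\mathit{MSS}_{\mathrm{err}})}{df\,\mathit{MSS}_{\mathrm{eff}} +
(N - df)\,\mathit{MSS}_{\mathrm{err}}},$$

reported verbatim even when negative; 95% bootstrap percentile intervals
come from resampling condition rows (the ANOVA's unit of analysis), 2,000
resamples by default, redrawing any resample that empties a factor level.
An effect is deemed practically important when its interval reaches 0.14,
the conventional large-effect threshold.

## What the generator does and does not emulate

The generator reproduces the study conditions exactly: normal factors and
errors, simple structure, standardized indicators, uniformly drawn
loadings, the seven interfactor correlations, the five sample sizes and
the three outcome families with $\gamma = (1, 2)$. It does not emulate
cross-loadings, correlated or non-normal measurement errors, more than two
factors, missing data, or model misspecification — so passing tests say
nothing about FSR behaviour under those violations. Real indicator data
are rarely exactly standardized multivariate normal; the criteria here
isolate scoring-method effects under the idealized measurement model, which
is the point of the design, not a claim of external validity.

## Problem sizes used in the checks

The full reference setting (3,780 conditions × 1,000 replications) is a
cluster-scale computation. The package's own verification runs the
measurement design at reduced replication counts, chosen as the smallest
sizes at which the Monte-Carlo error is a fraction of the agreement
tolerances used: the replication checks run all 315 measurement conditions
at 100 replications (50 in the test suite) with the method/link cells they
compare, and exact identities (score algebra, df layouts, effect-size
arithmetic) are checked at full precision where no simulation is needed.
At 100 replications the per-tail trim is 1 (ceiling of 0.5), slightly more
aggressive proportionally than 5/1,000, which nudges tail-sensitive
criteria (empirical Type I error especially) downward by up to ~2 points
in heavy-tailed cells; the comparison tolerances accommodate this.

## Known limitations

* ULS optimizer internals differ from other SEM software; borderline
  admissibility (hence nonconvergence rates) can differ at the margin even
  when rates agree at the design level.
* At weak loadings ($\mu_\lambda = 0.40$) with small samples, the ULS
  optimum can sit very close to a singular factor correlation
  ($|\hat\phi_{12}|$ of 0.94–0.996) while remaining admissible under the
  package's positive-definiteness tolerance. Profiling the discrepancy
  over $\phi_{12}$ shows these are genuine global optima, not optimizer
  artifacts. The resulting factor scores are nearly collinear, and the
  second-step coefficient estimates in those replications are heavy-tailed
  (occasionally an order of magnitude above the true value); trimming
  removes only part of that mass. The regression method's mean relative
  bias is the criterion most sensitive to this, and other software that
  screens or resolves such near-boundary solutions differently can report
  a few points more negative mean RB at the weak-loading corner. No
  boundary-proximity screen is applied here: every cutoff tried also
  flagged legitimate $|\phi_{12}| = 0.8$ replications, so the admissibility
  rules are kept exactly as stated above.
* The bootstrap unit is the condition row; resampling replications within
  conditions is a different (unimplemented) scheme.
* The per-replication seed encoding is collision-free on the canonical
  design lattice for up to 10,000 replications; arbitrary off-lattice
  parameter values fall back to a hash with no uniqueness guarantee.
* Parallel execution is not built in, but the seeding contract
  (replication-level streams independent of execution order) makes the
  loop embarrassingly parallel if a caller chooses to split the grid.
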