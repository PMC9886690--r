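---
title: "Model averaging for instrumented fall-risk prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model averaging for instrumented fall-risk prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallbma)
```

This vignette is the package's account of its statistical machinery:
the model, its assumptions, the parameters that matter, what the
synthetic cohort generator does and does not emulate, and the numerical
and design choices behind the implementation.

## The prediction problem

A case-control cohort of community-dwelling older men took a short
instrumented stand-and-walk (ISAW) test — 30 s of quiet stance, step
initiation, a 7 m walk, a 180° turn, and a 7 m return — wearing
inertial sensors. Seventeen pre-selected, non-redundant metrics
describe seven mobility domains: four postural-sway measures (`S`), one
anticipatory-postural-adjustment amplitude (`A`), two temporal (`G:T`),
two spatial (`G:S`), three variability (`G:V`) and three upper-body
(`G:U`) gait measures, and two turning measures (`T`). The outcome is
prospective faller status: at least one reported fall in the twelve
months after the test. The four sway metrics are right-skewed and are
carried on the natural-log scale everywhere — in the registry, the
generator, the descriptive tables and the models; `isaw_metrics()`
records the flag.

## The model average

With $p = 17$ candidate metrics there are $2^{17} = 131{,}072$ subset
models. Each model $m$ is a logistic regression

$$\operatorname{logit} \Pr(\text{faller}_i) = \beta_0 +
\boldsymbol{x}_{i,S_m}^\top \boldsymbol{\beta}_{S_m}
\; (+\; \gamma_1\,\text{age}_i + \gamma_2\,\text{prior falls}_i),$$

fitted by maximum likelihood, where $S_m$ is the metric subset and the
parenthesised base covariates are forced into every model in the
"history + age" scenario. The Bayesian Information Criterion
$\mathrm{BIC}_m = k_m \ln n - 2\ln \hat L_m$ converts to posterior
model probabilities under a uniform prior:
$w_m \propto \exp\{-(\mathrm{BIC}_m - \min_m \mathrm{BIC})/2\}$.

Reported aggregates:

* **Posterior inclusion probability** of metric $j$:
  $\mathrm{PIP}_j = \sum_{m \ni j} w_m$, the total weight of models
  containing the metric. Tables flag values above 0.40, a conventional
  "more likely in than chance would suggest" reporting threshold.
* **Model-averaged coefficients.** The default is the unconditional
  average ($\bar\beta_j = \sum_m w_m \hat\beta_{j,m}$ with
  $\hat\beta_{j,m} = 0$ when $j \notin S_m$), the standard BMA point
  estimate; the conditional average
  $\bar\beta_j / \mathrm{PIP}_j$ is exposed as a secondary field.
* **Model-averaged risk.** The default is the mixture predictive
  $\bar p_i = \sum_m w_m \hat p_{m}(i)$ — the proper Bayesian average
  of per-model probabilities. The alternative "plug-in" risk, the
  logistic function applied to the averaged coefficients, is also
  computed (`avg_risk_from_avg_coef`); the two differ because the
  logistic function is nonlinear. Published analyses of this design do
  not say which variant produced their curves, so both are available
  and the mixture is the documented default.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `include_history_age` | `FALSE` | force age (years) and prior-year fall count (count) into every model |
| `max_size` | unlimited | cap on subset cardinality |
| BIC sample size $n$ | analysis-subset rows | held constant across models so weights are well defined |
| $k$ | includes intercept | constant-in-$k$ offsets cancel in the weights |
| PIP flag threshold | 0.40 | reporting convention only |

### Numerical choices

Fits use iteratively reweighted least squares (`stats::glm.fit`) with
deviance tolerance $10^{-12}$ and at most 100 iterations — tight enough
that independently converged refits agree with the stored coefficients
to well below $10^{-10}$. Quasi-complete separation is flagged when
fitted probabilities reach the $10^{-8}$ boundary alongside
coefficients exceeding 15 in absolute value; non-converged or separated
fits are excluded from the average with renormalised weights and a
warning count. Weights are computed after subtracting the minimum BIC,
so no exponential can overflow, and models with infinite BIC receive
weight exactly zero. The averaged risk is accumulated over chunks of
4,096 models to bound memory at a few megabytes per chunk. Subset
enumeration is binary counting (subset $m$ contains metric $j$ iff bit
$j-1$ of $m$ is set), a deterministic order that tests can reproduce;
`top_models()` breaks exact BIC ties lexicographically by subset name.
Warm-starting each fit from its parent subset was considered and
rejected: plain fits complete the full 131,072-model space in about two
minutes on a single core, so the added state was not worth the
complexity.

## Descriptive layer

Group comparisons use the pooled-variance two-sample Student t-test
with $n_1 + n_2 - 2$ degrees of freedom, computable from published
summary statistics alone; it reproduces the published anchor p-values
(0.015 for log sway velocity, 0.011 for gait speed) at three decimals,
which a Welch test does not, so pooled is the default and Welch sits
behind a flag. No multiplicity correction is applied across the 17
tests, matching the source analysis. The fall-status cross-tabulation
dichotomises history at one or more prior-year falls; conditional row
percentages are reported to one decimal.

Dual-task cost is the signed percentage
$\mathrm{DTC} = 100\,(\text{dual} - \text{single})/\text{single}$:
slowing under a concurrent cognitive task is negative. Prose
conventions elsewhere quote magnitudes ("slowed turns by 13.33%"); the
package keeps the signed value and leaves interpretation to the caller.

## Discrimination

The AUC is the Mann–Whitney estimator
$P(\text{score}_{\text{faller}} > \text{score}_{\text{non-faller}}) +
\tfrac12 P(\text{tie})$, computed from midranks. ROC curves threshold
at every distinct score; ties are traversed diagonally so the
trapezoidal area equals the Mann–Whitney value exactly. All AUCs are
in-sample (apparent), matching the source design, which describes no
cross-validation; they are optimistic for external use.

Confidence intervals default to a stratified nonparametric bootstrap —
cases and controls resampled separately, percentile interval, 2,000
replicates, seeded — because the source's interval method is unstated
and the bootstrap is assumption-light. The DeLong closed form is
available (`method = "delong"`) and is cross-checked against `pROC` in
the test suite. Degenerate (constant) scores yield the interval
$[0.5, 0.5]$ with a warning. In simulation (binormal scores, true AUC
0.75, $n = 200$ per dataset, 500 datasets) the bootstrap interval
covers the truth about 93–94% of the time — the familiar slight
undercoverage of percentile intervals at this sample size.

The model frontier reports, for the lowest-BIC models, each model's
in-sample AUC against $\Delta\mathrm{BIC} = \mathrm{BIC} - \min
\mathrm{BIC}$ (best is zero), with median and maximum AUC grouped by
the number of metrics. Families of ROC curves are summarised by
vertical averaging on a fixed false-positive-rate grid (step 0.01)
followed by isotonic regression; the smoothing method behind the
published curves is not described, so this explicit, reproducible
stand-in is used instead.

## The synthetic cohort generator

Per-participant data from the source cohort are access-controlled, so
the generator emulates the published group-level structure and serves
as the package's test bed:

* **Group sizes** default to 123 non-fallers and 91 fallers (42.5%
  fallers among 214 analysable participants).
* **Metric marginals** are Gaussian on the analysis scale with the
  published per-group means and SDs, joined by a Gaussian copula.
  The default correlation is exchangeable $\rho = 0$ (independent):
  inter-metric correlations were never published, marginals drive every
  calibration test, and dependence is exposed as a sensitivity knob
  ($\rho > 0$ or a full positive-definite matrix).
* **Prior-year fall counts** follow a zero-inflated Poisson whose zero
  mass and rate are solved (by `uniroot` on one monotone equation) from
  the two published moments per group — $P(\geq 1 \text{ fall})$ of
  0.260 / 0.527 and mean counts $40/123$ / $125/91$ — then truncated at
  13, the published per-participant maximum. Sampling uses the
  equivalent hurdle form, so the non-zero fraction hits the configured
  probability exactly in expectation. The simplest two-parameter family
  matching both printed moments.
* **Ages** are drawn from a piecewise-linear quantile function through
  the per-group median and interquartile range (83 (80, 86) non-fallers,
  84 (80, 89) fallers) with range endpoints 78–96, rounded to whole
  years — only quantiles were published, so only quantiles are matched.
* **Dual-task values** invert the cost formula exactly:
  $\text{dual} = \text{single}\,(1 + \mathrm{DTC}/100)$ with per-group
  Gaussian DTC, applied on the natural scale (log-scale metrics are
  exponentiated first). Mean DTCs follow the published values (gait
  speed about $-20\%$ in both groups; turn velocity $-13.33\%$ in
  non-fallers versus $-3.14\%$ in fallers). Spreads are not published;
  the defaults — SD 10 percentage points for gait speed, 15 for turn
  velocity — were chosen once so that nearly all participants slow
  their gait while roughly half the fallers speed up their turns,
  matching the qualitative description of the cohort.
* **Missingness**: prospective status is set indeterminate
  independently with a configurable rate (the study lost 15 of 229);
  `analysis_subset()` removes such rows before modelling.
* **Determinism**: one master seed; each component (metrics, fall
  counts per group, ages per group, dual-task costs, missingness) draws
  from its own deterministically derived substream, and generation
  leaves the caller's RNG state untouched.

### What passing tests do and do not show

The generator reproduces *marginal* group structure. It does not
reproduce inter-metric correlation, age–metric dependence, or any
relationship between fall history and the metrics beyond their shared
group membership, because none of these were published. Consequently
the synthetic cohorts are *easier* to discriminate than the real one —
seventeen independent metrics, each carrying its own group separation,
jointly overstate the separation that correlated real metrics achieve —
and the full-scale model-average AUCs on synthetic cohorts (≈ 0.77
metrics-only at the default seed) sit above the real-data values they
structurally parallel. Calibration tests therefore validate the
machinery (weights, PIPs, averaging, ROC) and the generator's marginal
fidelity, not real-data discrimination, which would require the
access-controlled cohort.

## Problem sizes used in the test suite

Oracle-equivalence tests compare the engine with an independently coded
brute-force reference on model spaces up to $2^5 = 32$ models at
$n \approx 200$, where exhaustive enumeration by a second route is
cheap. Parameter-recovery tests use $n = 2{,}000$ with one true
predictor ($\beta = 1.5$) and four noise metrics over 50 seeds;
bootstrap coverage uses 500 simulated datasets of $n = 200$. The
full-scale determinism-and-normalisation check runs the complete
131,072-model space once on a 214-row cohort. Marginal-calibration
checks use $10^4$–$10^5$ draws, where the CLT and binomial bounds being
tested are sharp.

## Known limitations

* All AUCs are apparent; no optimism correction or external validation
  is implemented (an explicit non-goal — the source cohort's models are
  themselves unvalidated externally).
* The uniform model prior and pure-BIC weighting are fixed by design;
  no Occam's-window pruning, MCMC composition, or alternative priors.
* The generator's independence default means synthetic PIP patterns
  should not be read as estimates of the real cohort's PIPs.
* BIC's $\ln n$ penalty uses the analysis-subset size; with forced base
  covariates the penalty difference between nested models is unchanged,
  but comparisons across the two scenarios compare differently sized
  parameter spaces, as in the source analysis.
* The continuous prior-fall count is taken as supplied; the estimation
  rule that produced it from periodic fall reports is outside scope.
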