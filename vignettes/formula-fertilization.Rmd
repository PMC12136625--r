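---
title: "Formula fertilization analysis for '3414' NPK trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Formula fertilization analysis for '3414' NPK trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fert3414)
```

## The '3414' design

The '3414' scheme is the standard incomplete factorial of Chinese
soil-testing and formula-fertilization practice: three factors (N, P2O5,
K2O), four application levels each, fourteen treatments. Level 2 of each
nutrient is the locally optimal dose; levels 0, 1 and 3 apply 0, 0.5 and
1.5 times that amount. The fourteen treatments are chosen so that every
single-nutrient response (the other two held at level 2), every
two-nutrient response, and the full three-factor quadratic surface are
estimable, while the all-omission control and the single-omission
treatments double as soil-fertility diagnostics.

```{r}
build_3414_design(c(N = 30, P = 10, K = 16))
```

Doses are always expressed in grams per plant of N, P2O5 and K2O (the
fertilizer-trade oxide conventions), and yields in grams of fresh buds
per plant. The packaged example, `lonicera_trial()`, is a
three-replicate honeysuckle (*Lonicera japonica*) trial at level-2 doses
30/10/16 g per plant.

## Fertilizer effect functions

The workhorse model is the quadratic *fertilizer effect function*

$$ Y = b_0 + \sum_i b_i x_i + \sum_i b_{ii} x_i^2
     + \sum_{i<j} b_{ij} x_i x_j , $$

fitted by ordinary least squares of yield on dose polynomials.
`fit_effect_function()` fits any subset of the three factors over any
subset of treatments; the canonical subsets (single factors varied with
the others at level 2, factor pairs pooled over their varying
treatments, and all fourteen for the ternary surface) are provided by
`lonicera_fit_treatments()`.

Two design choices matter here:

* **Dose units, not coded levels.** Regressions run on g/plant. On the
  packaged trial the ternary intercept lands within a few grams of the
  unfertilized control mean (296.7 vs 295.8 g/plant), which is the
  signature of dose-unit fitting; coded-level fitting would decouple the
  intercept from the control.
* **Treatment means by default.** The fit uses per-treatment mean
  yields. On a balanced trial (equal replication everywhere) the
  coefficient vector is identical whether means or individual plots are
  fitted — a property the test suite asserts — so the choice only
  affects the residual degrees of freedom used in the F test. The F
  statistic compares model to residual mean squares with (p − 1, n − p)
  degrees of freedom on the fitted points.

Goodness of fit is reported as the coefficient of determination R².
Published tables in this literature alternate between labelling such
values "R" and "R²"; this package computes and reports R² only.

### Typicality and the law of diminishing returns

A fertilizer response obeying the law of diminishing returns has every
linear coefficient strictly positive and every pure quadratic
coefficient strictly negative: yield rises with the first grams of
nutrient and the marginal gain shrinks until it turns negative. Only
then does the *marginal-derivative* economic optimum — the dose where
the value of the marginal yield equals the nutrient's price,
$\partial Y/\partial x_i \cdot p_\text{crop} = p_i$ — exist and make
agronomic sense. `classify_typicality()` applies the sign rule with
strict inequalities (a coefficient of exactly zero is a violation; the
boundary case is documented rather than silently admitted), and
`marginal_optimum()` refuses atypical fits with an error pointing to
frequency analysis, mirroring how practitioners handle surfaces that
fail the sign check. `stationary_point()` is agnostic: it solves the
zero-gradient system $2Qx = -b$ for any nonsingular quadratic matrix and
labels the point maximum/minimum/saddle by the definiteness of $Q$.

On the packaged trial the ternary surface has a negative N linear term,
so it is atypical and the recommendation must come from frequency
analysis — which is exactly the situation the pipeline automates.

## Nutrient abundance and economics

The *relative yield* of a single-nutrient omission treatment (that
nutrient at level 0, the others at level 2) against the full-fertilizer
reference indexes the soil's own supply of the nutrient. The
conventional classes are: below 50% extremely low, 50–75% low, 75–95%
medium, 95% and above high. The published class ranges are open-ended;
this package fixes lower-inclusive bins so the classes partition the
axis and boundary values (exactly 75%, exactly 95%) classify
deterministically. `abundance_report()` also reports the per-gram yield
gain, (full − omission)/dose, of each omitted nutrient, and
`combination_gain_ranking()` ranks the nutrient pairs by the yield gain
of the treatment supplying exactly that pair at level 2 (descending,
with the fixed order PK, NP, NK breaking exact ties).

Economics follow three identities, computed unrounded and in CNY:

* output value = yield (g) × crop price (per kg) / 1000,
* fertilizer cost = Σ dose (g) × nutrient price (per kg) / 1000,
* profit-to-investment ratio = output value / cost (undefined for the
  zero-cost control, reported `NA`).

The USD view multiplies CNY quantities by the exchange fraction carried
in the `price_schedule` (0.1376 USD/CNY for the packaged trial, which
reproduces the quoted USD unit prices exactly). The "gain over control"
in USD is a *gross* output-value difference — fertilizer cost is not
subtracted — because that is the convention of the source trial's
reporting. Rounding to printed precision happens only in display code;
all stored values are full precision.

## Frequency analysis

When the fitted surface is atypical, the recommended dose is derived by
*yield-frequency analysis*: pick a target yield interval, count how
often each application level of each factor occurs among the individual
plots whose yields fall inside it, and summarize the hit doses by their
frequency-weighted mean

$$ \bar{x}_i = \frac{1}{n_j}\sum_j u_j\, n_{ij} , $$

standard deviation $S = \sqrt{\sum_j n_{ij}(u_j-\bar x_i)^2/(n_j-1)}$,
standard error $S/\sqrt{n_j}$, and the interval
$\bar x_i \pm z \cdot S/\sqrt{n_j}$ as the recommended range.

Numerical conventions, each exposed as a parameter:

* **Counting unit: the replicate plot**, not the treatment. With 14
  treatments × 3 replicates there are 42 countable plots; a single
  control plot falling below the interval's lower bound is what produces
  totals of 41 rather than 42 on the packaged trial.
* **Interval closure: both-inclusive by default.** The packaged
  default interval is [296, 413] g/plant — the rounded minimum
  treatment mean up to the maximum single-plot yield. The inclusive
  upper bound matters: one plot sits exactly at 413.
* **Quantile: normal 1.959964 by default.** The printed confidence
  intervals in this literature are reproduced by the large-sample
  normal quantile; the Student-t quantile with $n_j - 1$ degrees of
  freedom is available via `quantile_rule = "t"` and is slightly wider
  at these sample sizes (about 2.02 at 40 degrees of freedom).
* `freq_weighted_sd()` accepts an externally supplied mean, so a
  published mean can be pushed through the downstream formulas
  verbatim when auditing a report whose intermediate values do not
  reconcile (see Limitations).

`recommend_doses()` chains count → mean → SD → SE → CI per factor and
evaluates a ternary effect function at the point doses (the weighted
means, unless overridden) to give the predicted optimized yield.

```{r}
trial <- lonicera_trial()
rec <- recommend_doses(trial, yield_interval(296, 413),
                       lonicera_effect_functions()$NPK)
rec
```

## The synthetic-trial generator

`simulate_trial()` draws a '3414' trial from a known true quadratic
surface plus independent zero-mean Gaussian plot noise. It emulates
the structure of a real single-site trial: a balanced design, additive
homoscedastic replicate noise (the packaged trial's replicate spreads
of roughly 1–10 g around means of 300–400 g are approximately
homoscedastic, so a single shared standard deviation — default 5
g/plant — is used), and truncation of impossible negative yields at
zero with a warning counter. It does **not** emulate spatial field
trends, block effects, plot-edge effects, or heteroscedasticity, so
parameter-recovery results bound estimation error under ideal
randomization only; they say nothing about bias from field structure
in real data.

Noise draws use one deterministic stream per plot, seeded from the
root seed and the (treatment, replicate) pair, so enlarging
`replicates` extends a trial without perturbing existing draws, and
identical seeds give byte-identical trials.

`parameter_recovery_report()` wraps the simulate–refit loop and
reports per-coefficient bias and RMSE plus the rate at which the
refit's typicality verdict matches the true surface's. At the packaged
trial's scale (14 treatments × 3 replicates, noise 5 g/plant, 200
simulations) linear-coefficient biases are a few hundredths of a gram
per gram and the intercept RMSE is about 3 g/plant. The test suite
runs these studies at 60–200 simulations and replicate counts up to
300 — sizes chosen so the Monte-Carlo error of the checked summaries
is several times smaller than the asserted bounds.

## The pipeline

`run_full_analysis()` executes the whole chain in order — abundance
report, pair-gain ranking, economic report, all seven effect-function
fits with typicality verdicts and stationary points, the
marginal-derivative optimum when (and only when) the ternary fit is
typical, and the frequency-analysis recommendation — and optionally
writes every artifact as CSV/JSON plus a run log (package version,
seed, configuration; the timestamp lives only in the log so report
files are byte-identical across reruns). Configuration comes from
`pipeline_config()` or a YAML file via `load_pipeline_config()`;
unknown keys are rejected rather than ignored.

## Degenerate inputs and numerical choices

* Fits require at least as many points as coefficients and a
  full-rank polynomial design; failures raise errors naming the
  missing degrees of freedom or the collinearity, never silent `NA`
  coefficients.
* Stationary points require a nonsingular quadratic matrix
  (singularity tolerance: smallest eigenvalue below 1e-9 of the
  largest); the gradient at the solution is asserted below 1e-9 in
  relative norm.
* Least squares is solved by QR (`stats::lm.fit`); the test suite
  cross-checks every fixture fit against an SVD pseudoinverse oracle
  at 1e-8.
* Division-by-zero cases (zero reference mean, zero dose, zero
  fertilizer cost, empty frequency interval) raise errors; the
  economic report represents the control's undefined ratio as `NA`.

## Known limitations

* The packaged trial's published report is not perfectly
  self-consistent, and the package makes the discrepancies explicit
  rather than smoothing them over. The N-factor frequency counts
  (5, 9, 21, 2) cannot be produced by any counting rule that
  reproduces the P and K columns exactly (both give 5, 9, 24, 3 under
  inclusive [296, 413] plot-level counting); the N column is therefore
  treated as unreproducible, and the published N/P/K means
  (22.5/7.5/12) and the N standard deviation (13.17) are handled as
  fixed inputs to the SE/CI formulas rather than as recomputable
  outputs. The recomputed weighted means are 24.15, 8.05 and 12.88
  g/plant.
* The published single-factor table lists the N-factor maximum dose as
  7.5 g/plant, but the printed N function's vertex is 37.5 g/plant and
  reproduces the table's own maximum yield of 408.45 g/plant; the
  package reports the computed vertex. The K-factor maximum yield of
  445.99 g/plant is likewise not reproducible from the printed K
  function (vertex near 19.3 g/plant predicts about 400.7) and no
  reconciliation is attempted.
* Plot-level replicate yields are printed rounded to whole grams, so
  their means can differ from the two-decimal treatment means in the
  second decimal; the fixture stores both, and regression/economics
  default to the two-decimal means.
* No mixed-effects, spatial or block modelling; no cross-validation;
  no multi-objective (yield plus quality) optimization. Dose
  recommendations are point-in-time for one site, cultivar and season.
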