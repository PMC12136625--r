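# fert3414

Analysis of '3414' NPK formula-fertilization field trials in R.

The '3414' design — three factors (N, P2O5, K2O), four levels, fourteen
treatments — is the standard soil-testing and formula-fertilization
trial of Chinese agronomic practice: level 2 of each nutrient is the
locally optimal dose, levels 1 and 3 apply half and one-and-a-half
times that amount, and level 0 omits the nutrient. From one such trial
this package computes everything a fertilization recommendation needs:

* **Design and data handling** — `build_3414_design()`,
  `read_trial_table()` / `write_trial_table()` (CSV, one row per
  replicate plot), treatment means.
* **Fertilizer effect functions** — ordinary-least-squares fits of the
  quadratic response surface
  `Y = b0 + Σ bᵢxᵢ + Σ bᵢᵢxᵢ² + Σ bᵢⱼxᵢxⱼ`
  over any factor subset (`fit_effect_function()`), stationary
  (maximum-yield) doses (`stationary_point()`), classification against
  the law of diminishing returns (`classify_typicality()`), and the
  marginal-derivative economic optimum for typical surfaces
  (`marginal_optimum()`).
* **Abundance and economics** — relative-yield nutrient abundance
  indices and classes (`abundance_report()`), per-gram yield gains,
  nutrient-pair gain ranking, and output value / fertilizer cost /
  profit-to-investment economics (`economic_report()`).
* **Frequency analysis** — when the fitted surface violates
  diminishing returns, the recommended dose range per nutrient comes
  from counting plots inside a target yield interval
  (`count_frequencies()`), with frequency-weighted mean, SD, SE and
  confidence interval (`recommend_doses()`).
* **Synthetic trials** — `simulate_trial()` and
  `parameter_recovery_report()` generate trials from a known surface
  with Gaussian plot noise for end-to-end validation.
* **Pipeline** — `run_full_analysis()` runs every stage and writes a
  CSV/JSON report bundle.

The canonical example data set, `lonicera_trial()`, is a
three-replicate honeysuckle (*Lonicera japonica*) trial at level-2
doses 30/10/16 g per plant, with its price schedule
(`lonicera_prices()`) and the published effect functions
(`lonicera_effect_functions()`).

## Worked example

```r
library(fert3414)

trial <- lonicera_trial()

abundance_report(trial)
#>   treatment mean_yield relative_yield_pct omitted_factor abundance_class per_gram_gain
#> 1    N0P0K0     295.77           73.97394           <NA>             low            NA
#> 2    N0P2K2     338.53           84.66848              N          medium      2.043333
#> 3    N2P0K2     314.67           78.70095              P          medium      8.516000
#> 4    N2P2K0     322.73           80.71680              K          medium      4.818750
```

The unfertilized control yields 73.97% of the fully fertilized
treatment (the site's basic soil fertility); each omission treatment
sits in the 75–95% "medium" supply class, and each gram of P2O5 within
the tested range buys 8.52 g of fresh buds — phosphorus is the
limiting nutrient.

```r
fit <- fit_effect_function(trial, c("N", "P", "K"))
classify_typicality(fit)
#> atypical effect function; 1 sign violation(s):
#>  term expected_sign   observed
#>     N      positive -0.7491921
```

The ternary surface has a negative N linear term, so the
marginal-derivative optimum is refused and the recommendation comes
from frequency analysis:

```r
rec <- recommend_doses(trial, yield_interval(296, 413),
                       lonicera_effect_functions()$NPK)
rec
#> frequency-analysis dose recommendation (interval [296, 413] g/plant
#>   N: 24.15 g/plant (sd 12.04, se 1.88, 95% CI 20.46-27.83, n = 41)
#>   P: 8.05 g/plant (sd 4.01, se 0.63, 95% CI 6.82-9.28, n = 41)
#>   K: 12.88 g/plant (sd 6.42, se 1.00, 95% CI 10.91-14.84, n = 41)
#> point doses (g/plant): N = 24.15, P2O5 = 8.05, K2O = 12.88
#> predicted yield at point doses: 391.47 g/plant
```

41 of the 42 plots fall in the target interval (one control plot at
295 g sits below it); the weighted mean doses and their 95%
confidence intervals are the recommended ranges, and evaluating the
ternary surface at the point doses predicts the optimized yield.

```r
er <- economic_report(trial, lonicera_prices())
round(subset(er, treatment == "N2P3K2")[-1], 4)
#>   mean_yield output_value fertilizer_cost  ratio increase_vs_control_pct usd_gain_vs_control
#> 7      408.7       9.8088           0.362 27.096                 38.1817              0.3729
```

The best-yielding treatment (30 g N, 15 g P2O5, 16 g K2O) lifts yield
38.18% over the control, worth a gross 0.3729 USD per plant.

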