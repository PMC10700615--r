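# marshmf

Multifunctionality and trophic-cascade analysis for coastal wetland
restoration experiments.

## What problem does this solve?

Restoration experiments in coastal wetlands increasingly manipulate not just
vegetation (planting) but also trophic structure — excluding shorebird
predators, or excluding their crab-grazer prey to simulate historically
higher predation — and then ask whether treatments restored the ecosystem's
*multifunctionality*: the simultaneous provision of many functions, not just
plant cover. marshmf is for ecologists running such plot-based experiments.
It provides, in one tested pipeline:

* **Function estimators** — twelve ecosystem functions per plot from raw
  field measurements: primary production via the allometric ramet mass
  *M* = 0.0004 · *H*<sup>1.72</sup> plus core-scaled belowground biomass;
  secondary and microbial production; wave dissipation and heavy-metal
  reduction via the benefit transform −*f*<sub>i</sub> + max₃(*f*) (mean of
  the three largest values); sediment accretion from marker poles; carbon
  burial and nitrogen accumulation as accretion × element density; litter
  decomposition *k* from *L*<sub>t</sub> = *L*₀e<sup>−kt</sup>; nitrogen
  mineralization; infiltration; soil respiration; the Nemerow multifactor
  pollution index √((mean² + max²)/2) over seven metal contamination ratios.
* **Multifunctionality metrics** — the unweighted averaged index *A* of
  percent-of-maximum standardized functions (with above/belowground
  partitions), and Hill-number metrics on 0–1 standardized profiles: the
  effective number of functions
  *N*<sup>q</sup> = (Σ *p*<sub>i</sub><sup>q</sup>)<sup>1/(1−q)</sup> with
  *p*<sub>i</sub> = *F*<sub>i</sub>/Σ*F*<sub>i</sub>, its Shannon limit at
  *q* = 1, and effective multifunctionality
  <sup>q</sup>*M*<sub>ef</sub> = *N*<sup>q</sup> × *A*.
* **Treatment inference** — one-way ANOVA + Tukey HSD with compact letter
  displays, pairwise Wilcoxon (Bonferroni), pairwise proportion tests,
  first-week plant-loss slopes, AICc-selected linear/quadratic regressions,
  Spearman correlation matrices.
* **Trophic-cascade effect sizes** — log response ratios
  LRR = ln *X*<sub>P</sub> − ln *X*<sub>E</sub> with delta-method variances,
  DerSimonian–Laird random-effects pooling, monthly shorebird-exclusion
  effects on crab abundance, meta-regression of effects on bird abundance,
  and back-projection of historical grazer density
  *D*<sub>then</sub> = *D*<sub>C</sub> + [(*D*<sub>C</sub> −
  *D*<sub>E</sub>)/(*p·N*<sub>now</sub>)](*N*<sub>then</sub> −
  *N*<sub>now</sub>).
* **A seeded synthetic-data generator** emulating the 4-treatment × 8-plot
  design (function values, raw measurements, monthly crab/bird series,
  plant trajectories, tethering outcomes), so every stage is testable
  without field data. Real data in the documented CSV schemas are
  interchangeable with synthetic ones.

## Worked example

```r
library(marshmf)

ds  <- generate_experiment(experiment_config(seed = 1))
fm  <- build_function_matrix(ds$raw)
idx <- average_index(standardize_functions(fm, "percent_of_max"), "all")
anova_tukey(idx$avg_index, idx$treatment)
#> one-way ANOVA + Tukey HSD
#>   statistic = 179.8  df = 3, 28  p = <2e-16
#>   groups:
#> # A tibble: 4 × 3
#>   group                     mean letter
#>   <chr>                    <dbl> <chr>
#> 1 planting_predation_sim    66.8 a
#> 2 planting_control          40.2 b
#> 3 natural_recovery_control  37.3 bc
#> 4 planting_exclusion        35.3 c
```

Simulating high predation (crab exclusion) raises the averaged
multifunctionality index far above every other arm (letter "a"), while
planting alone is indistinguishable from natural recovery and shorebird
exclusion sits lowest — the treatment ranking the design encodes. The
monthly exclusion effect on crab burrows, pooled over three years with the
DerSimonian–Laird model:

```r
eff    <- exclusion_effect_on_crabs(ds$series)
pooled <- pooled_random_effects(eff$lrr, eff$var)
#> pooled exclusion LRR 0.66 [0.47, 0.86], tau2 0.300, k 36
```

A pooled log ratio of 0.66 means excluding shorebirds nearly doubled crab
abundance (e^0.66 ≈ 1.9), with the CI excluding zero; the heterogeneity
(tau²) reflects the seasonal coupling to bird migration. `run_pipeline()`
chains all stages and writes tidy CSV result tables.

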