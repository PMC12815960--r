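# ppmr

Predator–prey mass ratios (PPMR) from fish stomach-content records, across
gradients of sea-surface temperature (SST) and commercial fishing effort.

Marine food webs are strongly size-structured, and the ratio of a predator's
body mass to the mass of its prey constrains how energy flows through them.
This package implements a full stomach-content analysis pipeline for
DAPSTOM-style diet records from the Northeast Atlantic shelf seas: it

* computes the **biomass-weighted PPMR** of each predator stomach,

  PPMR = M_pred / ( (1/n) Σⱼ Mⱼ ),

  where the sum runs over all *n* prey individuals in the stomach (a prey row
  with count *k* and individual mass *m* contributes *k* individuals of mass
  *m*);
* assigns **ICES statistical rectangles** (0.5° latitude × 1° longitude,
  codes like `"31F4"`) and joins gridded monthly SST with a **one-month
  lag** (a stomach sampled in May is matched to the April cell mean) and
  annual fishing-effort hours per rectangle-year;
* fits **linear mixed-effects models** (via lme4) of the log10-transformed
  responses — PPMR, predator mass, individual prey mass, prey count, prey
  richness — on temperature, optionally with standardized log10 fishing
  effort and its temperature interaction, with random intercepts for
  rectangle, season, predator species, and (where applicable) stomach;
* classifies **per-species body-size responses** to temperature
  (increase / decrease / no change, as percent of species and percent of
  biomass), bins effort into equal-count **terciles**, and assigns prey
  **size classes** (small < 0.072 g ≤ medium < 1.25 g ≤ large);
* ordinates the family × rectangle prey community with **nMDS** on
  Bray–Curtis dissimilarities (via vegan) and fits environmental vectors
  (mean mass, temperature, effort) onto the configuration.

Because slopes are on the log10 scale, a temperature coefficient *b*
translates into a percent change of `(10^b − 1)·100` per °C and
`(10^(bΔ) − 1)·100` across a gradient of Δ °C (`pct_change_per_degree()`,
`pct_change_over_gradient()`).

A synthetic-data generator (`simulate_ppmr_data()`) emulates the three input
tables — stomach records, gridded SST, effort per rectangle-year — under a
known ground-truth model, with presets (`ppmr_preset()`) calibrated to the
fitted lines reported for the empirical Northeast Atlantic data. Every
downstream stage therefore has a parameter-recovery test.

The intended users are quantitative community ecologists working with diet
databases who want a tested, reproducible path from raw stomach rows to
mixed-model coefficients, rather than one-off scripts.

## Worked example

Simulate 2,000 stomachs under the PPMR preset (true model
log10 PPMR = 2.2 + 0.041·T), match covariates, compute per-stomach PPMR,
and fit the mixed model:

```r
library(ppmr)

sim     <- simulate_ppmr_data(ppmr_preset("paper_ppmr", n_stomachs = 2000, seed = 42))
matched <- match_covariates(sim$stomachs, sim$sst, sim$effort)
obs     <- compute_ppmr(matched)
obs[1:3, c("stomach_id", "predator_mass_g", "mean_prey_mass", "n_prey", "ppmr")]
#> # A tibble: 3 × 5
#>   stomach_id predator_mass_g mean_prey_mass n_prey  ppmr
#>   <chr>                <dbl>          <dbl>  <int> <dbl>
#> 1 s000001               164.          0.981      5  167.
#> 2 s000002               245.          0.376      4  651.
#> 3 s000003               255.          0.622      7  410.

fit <- fit_ppmr_model(obs, "log10_ppmr")
fit
#> <ppmr_fit> log10_ppmr ~ temp
#>   n = 1960 | AIC = 1496.8 | conditional R2 = 0.222
#> # A tibble: 2 × 6
#>   term        estimate std_error t_value    df   p_value
#>   <chr>          <dbl>     <dbl>   <dbl> <int>     <dbl>
#> 1 (Intercept)   2.18     0.0590    36.9   1958 3.70e-227
#> 2 temp          0.0382   0.00450    8.49  1958 3.90e- 17

report_fits(list(ppmr = fit), gradient = 15)
#> # A tibble: 1 × 6
#>   model stratum  slope std_error pct_per_degree pct_over_gradient
#> 1 ppmr  overall 0.0382   0.00450           9.20              274.
```

The fitted temperature coefficient (0.0382 ± 0.0045) recovers the generating
value 0.041 within one standard error; `report_fits()` back-transforms it to
a 9.2 % increase in PPMR per °C. The first stomach held 5 prey individuals
of mean mass 0.98 g in a 164 g predator, hence PPMR ≈ 167.

For a one-call run of every stage (simulate → match → PPMR → five response
models → species classification → nMDS → report), see
`run_ppmr_pipeline(ppmr_run_config(preset = "paper_ppmr", out_dir = "out"))`.

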