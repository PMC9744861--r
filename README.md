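# occutrends

Estimating multi-decadal distribution trends of insect species from
opportunistic records, and attributing those trends to climate and
regional land-use change.

Faunistic archives hold millions of opportunistic records — observations
collected by naturalists, experts and projects without a sampling
design. Changes in recording effort, observer skill and project focus
are confounded with real distribution change. `occutrends` implements,
as a tested and reusable R package, the full workflow needed to extract
distribution trends from such data and to decompose them by driver:

1. **Synthetic study system** (`sim_config()`, `simulate_dataset()`):
   a virtual landscape of 1×1 km squares in up to nine bioclimatic zones
   (biogeographic region × elevation class, split at 1000 m a.s.l.),
   zone-specific climate and land-use trajectories, species with
   temperature niches and habitat specialisation, latent occupancy
   dynamics with known ground truth, and an opportunistic observation
   process (power-law observer activity, five source classes,
   list-length effects) that emits records only for detections.
2. **Record preparation** (`filter_records()`, `build_visits()`,
   `select_species()`, `classify_observers()`,
   `build_detection_histories()`): the visit construct (one observer or
   project, one day, one square), adult-only and informative-square
   filters, the 25%-of-years species rule, the 2.5% expert-observer
   rules, and per-species visit eligibility (project coverage,
   5%–95% day-of-year window, occupied zones).
3. **Occupancy-detection models** (`fit_occupancy_model()`,
   `derive_mean_occupancy()`, `marginal_loglik()`,
   `check_convergence()`): per-species hierarchical models with
   logit(ψ) = intercept + elevation + elevation² + region and square
   random effects + zone-wise random-walk year effects, and
   logit(p) = intercept + day-of-year + list-length class + source
   class + year effect, fitted by Gibbs sampling in JAGS. Annual mean
   occupancy per zone and country-wide is derived from the parameter
   draws for every included square-year, with split-R̂ diagnostics.
4. **Trend estimation** (`fit_window_trend()`, `summarize_trends()`,
   `hdi()`): per-draw OLS trends over 40-year and 5-year windows,
   counts of increasing/decreasing species, declining/increasing
   quarter summaries, percent changes, and a bootstrap interval for the
   sign-change position.
5. **Drivers and traits** (`compute_bioclim()`, `climate_change()`,
   `gapfill_landuse()`, `landuse_variables()`, `standardize_changes()`,
   `species_temperature_index()`, `habitat_specialisation()`):
   BIO1/BIO4/BIO18 from monthly climate, 10-year-window climate changes
   per 5-year interval, GAM-gap-filled agricultural statistics,
   standardized zone × interval change variables, and the two species
   traits.
6. **Trend regression** (`build_design()`, `fit_trend_regression()`,
   `sensitivity_filter()`): sign-root transformed 5-year trends
   regressed on the six driver changes, traits, elevation and their
   interactions, with zone intercepts and species random intercepts and
   slopes — a blocked Gibbs sampler with conjugate Gaussian blocks.
   Three model versions handle species not associated to agricultural
   habitats.
7. **Counterfactual scenarios** (`make_scenarios()`,
   `predict_scenario()`, `scenario_r2()`): 17 scenarios (no change /
   single drivers / climate × land-use pairs / all observed) predicting
   40-year species trends; explained variance is the squared Pearson
   correlation with the observed long-term trends, per posterior draw.

`run_pipeline()` orchestrates all stages and writes CSV/JSON artifacts
with a seed-carrying manifest.

## Worked example

A small end-to-end run — 3 zones × 40 squares, 12 species across three
insect groups, 21 years — takes a few minutes:

```r
library(occutrends)

cfg <- sim_config(
  n_zones = 3L, n_squares_per_zone = 40L, n_years = 21L,
  n_species_per_group = c(butterfly = 6L, grasshopper = 3L, dragonfly = 3L),
  visit_intensity = 2.5, rng_seed = 7L)

res <- run_pipeline(cfg, outdir = "demo_run", seed = 99)

res$trend_summary$counts
#>   direction mean lower upper
#> 1  positive 8.19     5    10
#> 2  negative 3.81     1     6

head(res$scenarios[order(-res$scenarios$mean_r2), 1:2], 3)
#>               scenario   mean_r2
#> 17                full 0.7164318
#> 9 bio1+grass_intensity 0.3823154
#> 7       crop_intensity 0.3522098
```

Reading this output: of the 12 simulated species, on average 8.2 show a
positive 21-year occupancy trend (95% HDI 5–10 species across posterior
draws). The scenario table decomposes the explained variance of
long-term trends: predictions using all measured driver trajectories
align best with the observed trends (R² = 0.72), and single-driver
scenarios show which trajectories carry that signal. `demo_run/`
contains the per-species trend tables, the regression effect summaries,
the scenario table and a JSON manifest recording seeds, filter counts
and convergence fractions. At this demonstration scale the MCMC chains
are deliberately short; the manifest reports the fraction of derived
occupancy values passing the R̂ < 1.1 check.

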