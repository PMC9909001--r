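# natdisp

Natal dispersal — the movement from birth site to first breeding
site — is the dispersal event that matters most for gene flow and
population connectivity in birds, and one of the hardest to measure.
`natdisp` turns continental band-recovery data into comparable
per-species natal dispersal distances and asks what explains the
variation among species: flight efficiency (wing aspect ratio),
population size, habitat, diet, foraging style, body mass, migration,
range size.

The package provides, as composable tidyverse-style functions:

- **Record screening** — the filters that make a banding-to-recovery
  pair interpretable as natal dispersal (banded as nestling/fledgling,
  recovered as a mature adult, both events in the breeding season and
  breeding range, found dead, coordinate precision ≤ 1′ block), with a
  per-filter removal audit.
- **Geodesics** — a from-scratch vectorized Vincenty inverse on the
  WGS84 ellipsoid (km), validated against an independent geodesic
  library to 1e-6 relative error.
- **Dispersal estimates** — per species, the geometric mean distance
  exp(mean(ln d)), the SE of ln d, and mean years between banding and
  recovery; species with n < 5 are dropped.
- **Morphometrics** — wing aspect ratio AR = B²/A_tot with
  A_tot = 2A_w + C_r(B − 2E), aggregated to species means.
- **Phylogenetic GLS** — maximum-likelihood fits with Pagel's λ error
  structure (V(λ): off-diagonal shared branch lengths scaled by λ),
  AICc, the null-comparison R² = 1 − RSS_model/SS_null at the same λ,
  and a boundary-corrected likelihood-ratio test of phylogenetic
  signal.
- **Multimodel inference** — all-subsets enumeration with marginality
  (≤ 5 variables, interactions among continuous/binary predictors
  only), Akaike weights w_i ∝ exp(−Δ_i/2), 95% confidence model sets,
  variable importance (summed weights), conditional and full model
  averaging, and Fox–Monette GVIF^(1/(2 df)) collinearity diagnostics.
- **A synthetic-data generator** with known ground truth (log-normal
  dispersal kernels, labeled contaminant records, λ-structured traits
  on simulated phylogenies), so the whole pipeline is testable without
  restricted-access banding data.

## Worked example

Simulate a 44-species study (200 records per species, 5% contamination
per class, true slope 1 of log dispersal on the flight-efficiency
predictor `x1`, residual λ = 0.4), run it through the full stack:

```r
library(natdisp)

sim <- simulate_study(sim_config(seed = 1))

est <- filter_records(sim$records, sim$meta) |>
  estimate_dispersal() |>
  retain_species(5)
head(est, 4)
#> # A tibble: 4 × 6
#>   species     n geomean_km log_se mean_recovery_years n_floored
#> 1 sp01      160       26.3 0.0590                2.72         0
#> 2 sp02      160       20.4 0.0633                2.77         0
#> 3 sp03      160      123.  0.0546                2.69         0
#> 4 sp04      160       18.3 0.0615                2.73         0
```

160 of 200 records survive screening (4 contaminant classes at 5%
each), and the geometric means sit near each species' kernel median.
Regress log dispersal on the predictor with phylogenetic GLS:

```r
traits <- est |>
  dplyr::mutate(log_dispersal = log(geomean_km)) |>
  dplyr::left_join(sim$traits, by = "species")

fit <- pgls(log_dispersal ~ x1, traits, sim$tree)
glance(fit)
#>       n     k lambda sigma2 logLik  AICc r.squared   rss
#> 1    44     4  0.384  0.257  -29.4  67.9     0.757  11.3
tidy(fit)
#>   term        estimate std.error statistic  p.value
#> 1 (Intercept)    2.91     0.156       18.7 5.69e-22
#> 2 x1             0.977    0.0853      11.4 1.69e-14
```

The generating values (slope 1, λ 0.4, intercept 3, σ² 0.25) are
recovered. All-subsets model selection over the true predictor and two
noise predictors puts all the importance on `x1`:

```r
specs <- list(predictor_spec("x1"), predictor_spec("x2"),
              predictor_spec("x3"))
ms <- fit_model_set(traits, sim$tree, "log_dispersal", specs)
variable_importance(ms)
#>   variable importance
#> 1 x1            1.000
#> 2 x3            0.420
#> 3 x2            0.335
```

`run_full_pipeline(pipeline_config(...))` chains all stages and writes
the estimate table, filter audit, single-predictor comparison table,
ranked model table, confidence set, importance, averaged coefficients,
GVIF table and a manifest to disk;
`inst/scripts/dispersal-pipeline.R` wraps it for shell use with a YAML
config. `reproduce_benchmark()` runs the identical analysis stack on
an archived per-species dataset and tree.

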