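# aridpulse

Rainfall pulses, critical windows and bottom-up trophic cascades in
arid-savannah arthropod communities.

## The problem

In arid savannahs, rain falls as erratic pulses inside a short growing
season, and both the seasonal amount and the *timing* of those pulses
shape plant cover and the activity density of ground-dwelling
arthropods (pitfall-trap counts per plot and sampling round). This
package implements, as tested and reusable R functions, the complete
analysis chain of a multi-year pitfall study of this kind, for
ecologists who want to run, check, or power-analyse such designs:

* a seeded **synthetic-study generator** (30 plots x 6 years x 2
  trapping rounds by default) with daily rainfall, soil texture,
  vegetation surveys, NB-distributed counts per trophic group with
  known critical-window lags, bottom-up links, plot random effects and
  year-level variation;
* the **data rules**: ground-dwelling filter, exclusion of taxa with
  study totals below 50 individuals, per-plot-year summing of counts,
  per-plot-year vegetation maxima, Feb--Mar seasonal rainfall;
* a **Spearman collinearity screen** (|r_s| > 0.7, gradient-length
  preference rule);
* **community ordination**: unit-sum-of-squares column normalization,
  Bray--Curtis dissimilarity, 2-D NMDS minimizing Kruskal stress-1
  (PAVA + Guttman transform, 20 restarts, Procrustes convergence),
  environmental vector fitting with 1000 permutations, and
  sequential-SS PERMANOVA (McArdle--Anderson);
* the **moving-window critical-rainfall-window scan**: for widths
  {7, 14, 30} days and offsets 0--30 days before trap start, fit
  `count ~ windowed_rain + year + (1 | plot)` with a negative-binomial
  mixed model and profile a deviance-based adjusted R² --

  R² = 1 − D_full / D_null,  R²_adj = 1 − (1 − R²)(n − 1)/(n − p − 1),

  the offset with maximal R²_adj locating each group's critical
  window;
* the **bottom-up cascade suite**: six NB mixed models
  (plants, herbivores, omnivores, predators, detritivores, ants) with
  a tested / not-tested (NT) covariate mask and a starred summary
  table.

The methods vignette (`vignettes/arid-rainfall-windows.Rmd`) documents
the model, its assumptions, all tunable parameters and the numerical
choices.

## Worked example

```r
library(aridpulse)

study    <- gen_study(sim_config(seed = 1))
retained <- filter_taxa(study$traps, study$taxa)
records  <- aggregate_records(study$traps, study$veg, study$soil,
                              study$rainfall, study$taxa, retained)

## ordination
M   <- build_matrix(records)
D   <- bray_curtis(normalize_columns(M))
ord <- nmds(D, n_restarts = 20, seed = 7)
ord
#> NMDS: 158 sites, stress = 0.1490, 20 restarts, convergent

idx <- match(rownames(M), paste(records$plot, records$year, sep = "_"))
envfit_table(ord$scores, records[idx, reference_covariates()],
             n_perm = 1000, seed = 3)
#>            variable           r2       dir1       dir2     p_value
#> 1 seasonal_rainfall 0.4641296849 0.89520249  0.4456596 0.000999001
#> 2       plant_cover 0.3080958864 0.99400412 -0.1093426 0.000999001
#> 3            gravel 0.0151375624 0.07365686 -0.9972836 0.291708292
#> ...

## critical window for herbivores (true planted lag: 15 days)
rounds <- add_cover_response(rounds_table(study$traps, study$taxa,
                                          retained), study$veg)
prof <- scan_windows(rounds, study$rainfall, "herbivores",
                     widths = 7L, offsets = 0:30)
scan_summary(prof)
#>   width argmax_offset max_r2_adj plateau_from plateau_to
#> 1     7            14  0.6014041           14         14

## bottom-up cascade
fit_cascade(records)
#>                   plants  herbivores omnivores predators detritivores ants
#> seasonal_rainfall 0.56*** 0.82***    0.65***   n.s       0.85***      n.s
#> gravel            -0.24** n.s        n.s       n.s       n.s          n.s
#> plants            NT      0.67***    n.s       NT        0.31***      -0.20***
#> herbivores        NT      NT         n.s       0.58***   NT           n.s
#> ...
```

Reading the output: the ordination attributes community variation
mainly to seasonal rainfall and plant cover, not soil texture; the
scan places the herbivore critical window at 14 days before trapping,
one day off the planted 15-day lag; and the cascade table shows the
planted positive plants→herbivores and herbivores→predators links as
significant, with `NT` marking covariates excluded by the bottom-up
design.

The same chain runs as numbered drivers: `Rscript analysis/01_simulate.R`
through `analysis/05_cascade.R` (or `analysis/00_run_all.R`, which uses
`run_pipeline()` and writes a reproducibility manifest), with tables
under `results/`.

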