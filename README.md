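# qmricart

Serial multiparametric quantitative MRI (qMRI) analysis of articular
cartilage under compressive loading, as a tested, simulation-driven R
pipeline.

## The problem

Resting qMRI parameters (T1, T1ρ, T2, T2\*) separate intact from early
degenerative cartilage only weakly. Imaging the same sample at successive
loading positions — unloaded (δ0), 2.5 mm (δ2.5) and 5.0 mm (δ5.0) of
tibial displacement — turns the *response to loading* into a biomarker:
per-sample relative changes

Δ2.5 = (v(δ2.5)/v(δ0) − 1)·100 %,  Δ5.0 = (v(δ5.0)/v(δ0) − 1)·100 %

of zonal parameter means. `qmricart` implements the full chain for
researchers working on cartilage functional imaging:

1. **Synthetic cohort generator** — stadium-shaped 2D phantoms
   (8 mm × 3 mm disc, 80 × 80 grid, 0.375 mm pixels) with zonally
   stratified ground-truth relaxation fields, multiplicative loading shifts,
   Rician magnitude noise, Mankin histology scores and linear stress–strain
   curves; fully reproducible under a fixed seed.
2. **Relaxometry** — pixel-wise fits of S0·exp(−t/Tc) (T1ρ/T2/T2\*) and
   polarity-restored magnitude inversion recovery (T1), with the echo
   exclusion rule (first echo and TE > 60 ms dropped for T2/T2\*) and
   adjusted-R² fit-quality gating.
3. **Zonal ROI analysis** — boundary-pixel erosion, equal per-column
   superficial/deep partition, digital-caliper geometry, zonal means.
4. **Loading-response statistics** — log-transform with
   D'Agostino–Pearson normality check, repeated-measures ANOVA with Tukey
   post-tests across displacements, unpaired log-scale t-tests, Spearman ρ,
   and exact noncentral-t sample-size computation.
5. **Diagnostics** — intact-group mean ± SD reference intervals,
   per-sample classification ("positive" = reads intact), sensitivity /
   specificity, and believe-the-positive / believe-the-negative test
   combination.

## Worked example

```r
library(qmricart)

cfg    <- cohort_config(n_int = 27, n_deg = 22, seed = 42)
cohort <- generate_cohort(cfg, render = FALSE)        # truth-level cohort
wide   <- loading_response_table(cohort_truth_table(cohort))
tests  <- loading_response_tests(wide)
subset(tests, group == "deg" & zone == "dp",
       select = c(parameter, n, mean_d0, `mean_d2.5`, `mean_d5.0`, p_value, label))
```

```
 parameter  n mean_d0 mean_d2.5 mean_d5.0 p_value label
        T1 22 789.012   762.099   734.071   0.005    **
     T1rho 22  89.423   100.716   112.297   0.000   ***
        T2 22  42.053    45.499    49.085   0.000   ***
    T2star 22  23.479    22.658    23.945   0.284    ns
```

Deep-zone values of the degenerative group: T1 falls significantly under
loading while T1ρ and T2 rise significantly and T2\* does not — the
qualitative response pattern of the source cohort. The p-values are
repeated-measures ANOVA across the three displacements on log values;
`label` is the usual \*/\*\*/\*\*\* stratification.

```r
sample_size_unpaired(power = 0.9, alpha = 0.05, effect_size_d = 0.8)
#> [1] 34     # minimum per-group n by exact noncentral-t power

rep <- diagnostic_report(wide, zone = "ECS", scale = "log",
  combinations = list(list(tests = c("T2", "T2star:delta5.0"),
                           rule = "believe_positive")))
subset(rep$performance,
       test %in% c("T2", "T2star:delta5.0",
                   "T2+T2star:delta5.0|believe_positive"),
       select = c(test, sensitivity, specificity))
```

```
                                test sensitivity specificity
                                  T2       0.630       0.682
                     T2star:delta5.0       0.815       0.409
 T2+T2star:delta5.0|believe_positive       1.000       0.273
```

Combining the unloaded T2 test with the T2\* Δ5.0 response under the
believe-the-positive rule raises sensitivity (for intactness) at the cost of
specificity, exactly the trade-off the rule is designed for.

For image-level work use `generate_cohort(cfg, render = TRUE)` and
`pipeline_cohort_table()`, which rasterises every phantom, fits all maps
pixel-wise and returns the same tidy zonal table from measured images.

## Command line

```sh
Rscript -e 'qmricart::qmricart_cli()' simulate --n-int 27 --n-deg 22 --seed 1 --out runs/c1 --no-render
Rscript -e 'qmricart::qmricart_cli()' analyze  --table runs/c1/truth.csv --out runs/c1
Rscript -e 'qmricart::qmricart_cli()' diagnose --table runs/c1/truth.csv --out runs/c1
Rscript -e 'qmricart::qmricart_cli()' report   --table runs/c1/truth.csv --out runs/c1
```

## Documentation

The methods vignette (`vignettes/qmricart-methods.Rmd`) documents the signal
models, the fitting strategy, what the synthetic cohort does and does not
emulate, every defaulted assumption (noise level, shift variability,
quality threshold) and the package's design decisions.
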