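# variophen

Variogram-based texture quantification and phenotyping of lung CT.

Diffuse parenchymal lung diseases such as sarcoidosis change the spatial
texture of the lung on CT before, or independently of, changes in summary
intensity measures. `variophen` quantifies that texture geostatistically:
for each masked axial slice of each lung it estimates the empirical
variogram

γ(h) = ½ · E[(z_i − z_j)²],   for voxels i, j a distance h apart,

over in-plane voxel pairs up to a 25 mm cutoff (15 equal-width distance
bins), optionally after removing a fitted planar drift (HU ~ x + y). The
binned semivariances are used directly as features, or summarized by
weighted-least-squares fits of the exponential and Matérn variogram models

γ(h; θ) = σ² · (1 − ρ(h)),   ρ(h) = 2^(1−κ)/Γ(κ) · (h/r)^κ · K_κ(h/r),

with the nugget fixed at 0, Cressie weights N_j / γ(h_j; θ)², and the
smoothness κ searched over the grid 0.01–5 in steps of 0.01 (κ = 0.5 is the
exponential model). Per subject this yields, at 9 decile slices per lung,
270 empirical features, 36 exponential features (log sill and log range,
z-scored), or 54 Matérn features (plus raw κ).

Around this core the package implements the full phenotyping design:

- slice trimming (end slices with fewer than 1000 masked voxels at clinical
  scale) and decile slice selection;
- 24 feature datasets: {empirical, exponential, Matérn} × {raw, linear
  drift} × {registered, unregistered masks} × {unharmonized, harmonized};
- ComBat-style empirical-Bayes scanner harmonization preserving Scadding
  stage, height, age, BMI and sex;
- sparse diagonal Gaussian mixture clustering with per-feature relevance
  selection, K = 1–8, model selection by BIC or MICL (48 analyses);
- feature robustness (ICC(3,1), Spearman) across matched dataset pairs,
  bias-corrected Cramér's V and simulated Fisher tests for cluster
  associations, and a four-model outcome battery (linear regression with
  likelihood-ratio tests for lung function; Firth logistic regression with
  penalized likelihood-ratio tests for visual scores);
- a synthetic-cohort generator (Gaussian random fields with known Matérn
  covariance, planted phenotype clusters, scanner batch effects, linked
  outcomes) so every stage is testable without patient data.

## Worked example

```r
library(variophen)

# one masked slice: empirical variogram + Matérn fit
field <- simulate_grf_slice(c(psill = 1, range = 5, kappa = 0.5),
                            shape = c(48, 48), seed = 1)
idx <- which(matrix(TRUE, 48, 48), arr.ind = TRUE)
ev <- empirical_variogram(as.vector(field),
                          cbind(idx[, 2], idx[, 1]),
                          cutoff = 25, n_bins = 15)
fit <- fit_variogram_wls(ev, "matern")
glance(fit)
#> # A tibble: 1 × 8
#>   family psill range kappa nugget  wsse converged valid
#>   <chr>  <dbl> <dbl> <dbl>  <dbl> <dbl> <lgl>     <lgl>
#> 1 matern  1.08  3.02  1.01      0 2938. TRUE      TRUE
```

The generating field had partial sill 1, range 5 mm and κ = 0.5. A single
slice recovers the sill well (`psill` 1.08) while κ and range trade off
(1.01 and 3.0 mm here) — a smoother, shorter-range Matérn mimics the
exponential model over the observed lags, which is exactly why the median
over replicate slices, not a single fit, is the meaningful recovery check
(see `scripts/acceptance.R`: median fitted sill 0.99, range 4.7 mm over 50
slices at seed 1). `autoplot(ev, fit)` overlays the fitted curve on the
binned semivariances.

The full design runs from one configuration object:

```r
cfg <- cohort_config(seed = 1)       # 60 subjects, 3 planted clusters
report <- run_pipeline(cfg, out_dir = "results/pipeline")
report
#> <variophen_report> 60 subjects (60 retained), 24 datasets, 48 cluster analyses
```

`report$scanner_assoc` holds per-feature scanner R² (≈ 0 after
harmonization), `report$robustness` the matched-pair ICC(3,1)/Spearman
table, `report$cluster_consistency` the pairwise Cramér's V of the 48
analyses, and `report$outcomes` the base / Scadding / cluster / full model
fits with their nested-test p-values.

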