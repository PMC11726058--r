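---
title: "Variogram-based texture phenotyping: models, design choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variogram-based texture phenotyping: models, design choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(variophen)
```

## The model

A masked axial CT slice is treated as a partial realization of a
stationary, isotropic random field of Hounsfield units. Under stationarity
the semivariance

$$\gamma(h) = \tfrac12\,E\big[(z_i - z_j)^2\big] = C(0) - C(h)$$

depends only on the in-plane distance $h$ between voxels $i$ and $j$, where
$C$ is the field's covariance function. `empirical_variogram()` estimates
$\gamma$ by the classical binned (Matheron) estimator: all unordered
within-mask voxel pairs up to a 25 mm cutoff are assigned to 15 equal-width
distance bins, and each bin reports half the mean squared difference
together with the mean pair distance (the bin's representative $h$ — the
mean-distance convention, not the midpoint, matters in bins with few
pairs). When a planar trend violates the constant-mean assumption,
`drift_mode = "linear"` first replaces the values by ordinary
least-squares residuals of $z \sim x + y$.

Two parametric families summarize the estimate. The Matérn correlation in
the classical geostatistics parameterization is

$$\rho(h) = \frac{2^{1-\kappa}}{\Gamma(\kappa)}\,
  \Big(\frac h r\Big)^{\kappa} K_\kappa\Big(\frac h r\Big),$$

with range $r > 0$ and smoothness $\kappa > 0$; $\kappa = 0.5$ gives the
exponential model $e^{-h/r}$. (A Stein/Handcock-style reparameterization
exists in other software; fitted $\kappa$ and $r$ are comparable only
within the classical convention used here.) The variogram model is
$\gamma(h;\theta) = \sigma^2(1 - \rho(h))$ with the nugget fixed at zero:
the estimated fields are smooth at the voxel scale and the noise floor is
absorbed into the fitted sill.

### Weighted least squares

`fit_variogram_wls()` minimizes
$\sum_j w_j\,(\hat\gamma(h_j) - \gamma(h_j;\theta))^2$ with Cressie-type
weights $w_j = N_j / \gamma(h_j;\theta)^2$ ($N_j$ = pairs in bin $j$).
Because the weights depend on $\theta$, they are recomputed by iteratively
reweighted least squares: given weights, the inner problem is solved by a
damped Newton iteration on $\log r$ with $\sigma^2$ profiled out in closed
form; the outer loop repeats until the relative change in the weighted SSE
falls below $10^{-8}$ (at most 200 passes, with early exit when the
reweighting fixed point cycles). Initialization is the maximum empirical
semivariance for $\sigma^2$ and $r = 1$ mm. $\kappa$ is not fit
continuously: every value of the grid $0.01, 0.02, \ldots, 5$ is fit and
the grid point with smallest weighted SSE wins, ties going to the smallest
$\kappa$. Since $0.5$ is on the grid, the Matérn fit can never be worse
than the exponential fit on the same bins.

Two numerical choices keep the 500-point grid affordable over thousands of
slices: adjacent grid points warm-start each other (with periodic fresh
starts from the canonical initialization, and always at $\kappa = 0.5$),
and $\log(1-\rho)$ is tabulated per $\kappa$ on a log-distance grid with
cubic interpolation (relative error well below the sampling noise of any
empirical variogram); $\kappa = 0.5$ always uses the exact exponential
form, so the grid fit there coincides with the exponential fit and the
nesting inequality is preserved by construction. Profiling $\sigma^2$ leaves it unconstrained, so a
decreasing empirical variogram can legitimately produce a negative fitted
sill; such fits are flagged `valid = FALSE` rather than raised, and
subject exclusion is handled at the feature-engineering level.

## From images to 24 datasets

Per lung, end slices with fewer than `min_voxels` masked voxels are
trimmed (contiguously from the ends only; interior dips survive), and the
nine decile slices are taken at positions $\mathrm{round}(k n / 10)$,
$k = 1..9$, of the $n$ retained slices with round-half-up — the verbal
"ten equal height segments" rule admits several index conventions, and
this one is fixed here for reproducibility. Eighteen lung-decile slices
per subject times 15 lags give $p = 270$ empirical features; the
exponential fits give $p = 36$ (sill and range per lung-decile) and the
Matérn fits $p = 54$ (plus $\kappa$).

Sill and range are right-skewed, so they are log-transformed and z-scored
per column; $\kappa$ is already a bounded grid value and enters raw and
unstandardized (whether the original analyses standardized it is not
documented; the choice here is fixed and stated, not asserted as theirs).
Standardization statistics are computed on the unharmonized retained
cohort and frozen. A subject with any failed slice or any invalid
(non-positive) fit in any dataset is excluded from **all** datasets, so
the 24 datasets always cover one common subject set — the comparability
requirement that drives the whole design.

Datasets multiply along four axes: data type (empirical / exponential /
Matérn), drift handling (raw / linear residuals), mask registration
(subject-native masks vs a shared template mask), and scanner
harmonization (below): $3 \times 2 \times 2 \times 2 = 24$.

## Harmonization

`combat_fit_apply()` implements parametric ComBat: per feature, a location
model with batch (scanner) indicators and preserved covariates — Scadding
stage as a 5-level categorical, height, age, BMI, sex — is fit by least
squares; data are standardized by the grand mean, covariate effects and
pooled variance; per-batch location and scale effects are shrunk by
empirical Bayes (normal prior on locations, inverse-gamma on scales,
moment-matched hyperparameters, fixed-point updates to $10^{-6}$, at most
500 iterations); the adjusted data are rescaled and the covariate effects
restored. Subjects with missing covariates are dropped from harmonized
datasets only, so harmonized and unharmonized analyses can have slightly
different denominators, as in any complete-case design. The implementation
is cross-checked in the tests against an independent reference
implementation to ~1e-4 on simulated batch effects.

## Clustering with variable selection

The phenotyping model is a mixture of diagonal Gaussians over the
*relevant* features, with each *irrelevant* feature following a single
Gaussian common to all clusters (one mean and one variance — the
homoscedastic-irrelevance convention). For fixed $K$ and relevance,
`fit_gmm_diag()` runs EM from 20 k-means++-style seedings (performed on
internally standardized features, which makes the whole fit equivariant
under per-feature affine rescaling); emptied components are re-seeded from
the least well-explained subject, and starts whose variances collapse are
discarded.

`select_model()` searches $K = 1..8$, alternating an EM fit with a
per-feature relevance toggle given the current partition. Under BIC
(maximization convention, $\mathrm{loglik} - \tfrac{d}{2}\log n$ with
$d = (K-1) + 2K\,p_{\mathrm{rel}} + 2\,p_{\mathrm{irr}}$) the toggle
compares the clustered model (within-cluster MLE Gaussians, penalty
$K \log n$ per feature) against the common model (penalty $\log n$).
Under MICL the score is the integrated complete-data likelihood of the
hard partition: conjugate Normal-inverse-Gamma marginals per feature
block, a symmetric Dirichlet(1/2) prior on the label vector, and the
partition itself optimized by iterated conditional modes over single
subjects with incremental sufficient statistics (at most 100 passes). The
NIG hyperparameters are unit-information values centered on each feature's
empirical mean and variance ($\kappa_0 = 1$, $a_0 = 1$, $b_0$ = empirical
variance) — the reference clustering software does not document its
internal schedule or priors, so these are this package's own documented
stand-ins satisfying the same objective, and are exposed as arguments. A
$K$ whose every EM start degenerates (more components than the data
support) is recorded as infeasible and skipped. Ties in the criterion go
to the smaller $K$.

## Association battery

All comparisons are tidy tables produced by `run_pipeline()`:

- **Scanner association**: one-way ANOVA $R^2$ and F-test p per feature
  (vectorized; a constant feature reports $(0, 1)$ by convention).
- **Robustness**: two variables from different datasets are *matched* if
  they describe the same lung-decile and the same quantity (same lag bin,
  or the same model parameter; sill and range match across exponential and
  Matérn, $\kappa$ only Matérn-to-Matérn, empirical never matches model).
  Matched pairs get ICC(3,1) — two-way model, single measurement,
  consistency — and Spearman's rank correlation.
- **Cluster associations**: bias-corrected Cramér's V (Bergsma) and Fisher
  exact tests with simulated p-values (20 000 fixed-margin tables via
  Patefield sampling; a replicate counts as extreme when its
  hypergeometric probability is at most the observed one, the table-
  probability ordering convention; $p = (1 + \#\mathrm{extreme}) /
  (n_{\mathrm{rep}} + 1)$) for categoricals, F-tests for continuous
  covariates.
- **Outcomes**: per outcome, four models — base (sex, height, age, BMI),
  Scadding-only, cluster-only, full — with $R^2$ and likelihood-ratio
  tests for the continuous lung-function outcomes, and training AUC
  (midrank Mann–Whitney, hence invariant to monotone score
  transformations; reported as optimistic by construction, no
  cross-validation variant is offered) with penalized likelihood-ratio
  tests for the binary visual scores via Firth logistic regression. Firth
  fits maximize the Jeffreys-penalized likelihood by Newton steps with
  step-halving and stay finite under complete separation; the
  intercept-only fit with $y$ successes of $n$ equals $(y + 1/2)/(n+1)$.
  The penalized LRT scores the reduced hypothesis as a constrained fit of
  the full design (tested coefficients fixed at zero, the Jeffreys penalty
  always computed from the full design's information): comparing penalized
  likelihoods whose penalties come from designs of different dimension
  inflates the null statistic, whereas the profile version is
  well-calibrated (null p-values uniform in the tests). Complete-case
  analysis is applied per assessment, and a grouping with a single level
  (for example a one-cluster analysis) contributes no parameters, so its
  nested tests degenerate to $p = 1$ rather than failing.

## The synthetic cohort

Real masked CT cohorts of this kind cannot be redistributed, so the
package ships a generator whose defaults define the study conditions used
in tests and in `scripts/acceptance.R`: 60 subjects, 30 axial slices of
48 × 48 voxels at 1 mm, 3 planted phenotype clusters, 4 scanner models.
Each slice is an exact draw of a stationary Gaussian random field with the
cluster's Matérn covariance (dense Cholesky with $10^{-8}$ jitter up to
$128^2$ voxels, Dietrich–Newsam circulant embedding above), plus
independent voxel noise (SD 5 HU), a mild planar drift (0.5, −0.5 HU/mm —
nonzero by default so raw and drift-corrected variograms genuinely
differ), a parenchymal level of −800 HU, and the scanner's location/scale
effect (shifts 0/15/−10/25 HU, scales 1/1.05/0.95/1.1 — acquisition-level
confounding applied in image space, not feature space). Cluster textures
(psill 400/900/1600 HU², range 3/6/10 mm, κ 0.5/1.0/1.5) differ in all
three parameters so sill, range and smoothness features all carry signal;
the spacing is chosen so clusters are clearly separable at desk scale
without being trivial at the single-slice level.

Masks are two vertically stacked ellipses per slice whose area follows a
smooth $\sin^{1.5}$ cranio-caudal profile, tapering below the trimming
threshold at both ends so trimming is always exercised. At this grid size
the clinical threshold of 1000 voxels is replaced by 300 — scaled to the
slice area **and** chosen so every retained slice spans the 25 mm cutoff,
keeping all 15 lag bins populated; an end slice that cannot span the
cutoff would otherwise exclude its subject. "Registered" images share one
template mask; "unregistered" images perturb ellipse centers (±1.5
voxels) and axes (±8%) per subject. Outcomes follow the models the
analysis assumes: linear in cluster indicators and centered demographics
for the four lung-function measures (the default FEV1 cluster effects span
about two residual SDs), Bernoulli-logit for the nine binary visual
scores; about 3% of Scadding, lung-function and visual-score values are
set missing to exercise the complete-case paths.

What the generator does **not** emulate: lung anatomy, lesion morphology,
reconstruction kernels, non-stationary disease gradients beyond planar
drift, and registration as an image transformation (only as a mask
choice). Passing tests therefore demonstrate that the estimation,
harmonization, clustering and testing machinery is correct under the
model's own assumptions — not that those assumptions describe sarcoid
lung, a question the synthetic design cannot answer.

## Problem sizes and determinism

The default desk-scale design (60 subjects, 24 datasets, 48 analyses,
20 000-replicate Fisher tests, 20 EM starts) runs in a few minutes on one
core; the test suite uses smaller cohorts for unit checks and the default
cohort for the end-to-end determinism check. Every random step takes a
seed derived from one master seed (32-bit linear mixing), and
`run_pipeline()` writes no timestamps, so identical configurations
reproduce every output file byte for byte.

## Known limitations

- Variograms are 2D within-slice and isotropic; anisotropy and
  cross-slice (3D) structure are not modelled, and the nugget is fixed at
  zero by design.
- The WLS $\kappa$ search is a grid, so $\kappa$ is only resolved to 0.01
  and inherits the classical-parameterization convention.
- MICL optimization is a deterministic ICM stand-in for an undocumented
  reference schedule; it satisfies the same objective but may differ on
  near-ties.
- Training AUC is optimistic by construction; no out-of-sample variant is
  provided.
- With 60 subjects and up to 270 features, large-$K$ mixtures can be
  genuinely unsupported; such $K$ are reported as infeasible rather than
  forced.
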