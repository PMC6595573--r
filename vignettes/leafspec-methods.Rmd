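---
title: "Estimating leaf traits from VIS-NIR-SWIR spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating leaf traits from VIS-NIR-SWIR spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Full-range leaf reflectance spectroscopy (visible through shortwave
infrared, 350-2500 nm) is a fast, nondestructive proxy for leaf
physiological and chemical traits. Photosynthetic pigments absorb in the
VIS; leaf water absorbs in the SWIR (most prominently near 1450 and
1900 nm, with weaker overtones near 970 and 1240 nm); dry-matter
constituents (proteins, structural carbohydrates) produce combination and
overtone bands in the 2000-2400 nm region. `leafspec` implements a
complete spectra-to-trait calibration workflow for six leaf traits of a
cereal crop grown across contrasting environments: chlorophyll content
(CHL, umol/m^2), leaf water content (LWC, %), specific leaf area (SLA,
m^2/kg), and nitrogen, phosphorus and potassium concentrations (%, dry
mass basis).

The workflow is: replicate-scan averaging, spectral preprocessing,
whole-spectrum calibration by PLSR and linear epsilon-SVR with
cross-validated model selection, two-band vegetation-index baselines
including an exhaustive band-pair search, and evaluation by R^2, RMSE,
MAPE and RPD with a four-tier RPD quality grading.

# Data model and preprocessing

A raw scan lives on the 1-nm grid 350..2500 nm (2151 points). Nine scans
per plant (three leaves, each measured at tip/middle/base) are averaged
band-wise into one spectrum per plant; all nine are treated symmetrically.

Preprocessing (defaults in `preprocess_config()`):

* **Trim to 450-2500 nm.** The short-wavelength edge of contact-probe
  spectra carries elevated detector noise and is discarded.
* **Savitzky-Golay smoothing**, window 5 bands, polynomial order 2.
  Each band is replaced by the center value of a moving local quadratic
  least-squares fit; the two bands at each end are produced by the
  asymmetric rows of the projection matrix (a fit over the first/last full
  window evaluated off-center), so no bands are lost. The implementation
  delegates to `signal::sgolayfilt()`; the package's tests pin down the
  filter's algebra (exact reproduction of quadratics, the interior
  impulse stencil (-3, 12, 17, 12, -3)/35).
* **Downsampling to 5 nm** by decimation of the smoothed values anchored
  at 450 nm, giving 411 bands. Decimation (rather than block averaging)
  is the plain reading of "downsampling" after an explicit smoothing
  step, and keeps every retained band an actual instrument wavelength.
* **Standardization.** Predictors and response are zero-centered and
  scaled to unit variance using the *sample* standard deviation (n-1).
  Statistics are always computed on the training split only and reused on
  held-out data; during cross-validation they are re-estimated on each
  fold complement. Training-only scaling is the stricter of the two
  readings of "standardize before modeling" and is the one that cannot
  leak test information.

# Whole-spectrum calibration

## PLSR (NIPALS)

`fit_plsr()` implements univariate-response NIPALS with X- and
y-deflation, written out in `nipals_pls()`: weights
`w_a = X' y / ||X' y||`, scores `t_a = X w_a`, loadings
`p_a = X' t_a / t_a't_a`, `q_a = y' t_a / t_a't_a`, deflation
`X <- X - t_a p_a'`, `y <- y - q_a t_a`. Regression coefficients for every
truncation level are accumulated with the standard recurrence so one fit
yields all candidate models at once. NIPALS was chosen over SIMPLS for
transparency: every quantity has a small closed-form oracle (at full rank
the coefficients must equal ordinary least squares, scores must be
orthogonal, weights unit norm), which the test suite asserts.

Up to 25 latent variables are considered. The selected count minimizes
the 10-fold cross-validated RMSE, pooled over all held-out residuals
(`sqrt(mean(e^2))` over the full training set) rather than averaged per
fold - both conventions are defensible; pooling weights every sample
equally and is what a single held-out RMSE estimator converges to. Ties
go to the smaller model.

## Linear epsilon-insensitive SVR

`fit_svr()` solves the L1-loss linear SVR in standardized space. The bias
is carried as an extra constant feature appended to the design (i.e. it
is mildly regularized), which removes the equality constraint from the
dual and leaves a pure box-constrained QP:

min over beta in [-C, C]^n of
`1/2 beta' K beta - y' beta + eps ||beta||_1`, with `K = X X'` and
`w = X' beta`.

The solver is a randomized dual coordinate descent (compiled via Rcpp)
working on the n x n Gram matrix - the right regime for spectra, where
bands far outnumber samples. It stops when the relative duality gap falls
below 1e-6 or after 10,000 sweeps; hitting the cap is recorded in the
model metadata (common at tight tolerances on highly collinear spectra;
the remaining gap is typically ~1e-4, far below the cross-validation
noise floor). The in-sweep shuffle uses an internal xorshift generator so
results are bit-identical across platforms for a given seed. The test
suite checks the solution against `kernlab::ipop()` solving the same dual
as a generic QP, and against the KKT-implied zero-loss solution on exactly
linear data.

C is selected from {0.01, 0.1, 1, 10, 100} by the same pooled 10-fold
RMSE_CV; epsilon defaults to 0.1 in standardized response units (the
conventional default for this model family), exposed as a parameter.

## Vegetation indices

`builtin_vis()` provides GNDVI (800/550), RENDVI (750/705) and NDWI
(860/1240), all of the normalized-difference form
`(R_B1 - R_B2)/(R_B1 + R_B2)`. Calibration against a trait uses ordinary
least squares on `[1, v, v^2]` - the quadratic term absorbs the mild
saturation nonlinearity typical of such indices.

`exhaustive_band_search()` evaluates all unordered band pairs of the
processed grid (411 bands, 84,255 pairs), correlating
`(R_long - R_short)/(R_long + R_short)` with the trait on training
samples only, and returns the pair with maximal |r| (ties to the
lexicographically smallest pair). The search runs on the 5-nm processed
grid: the dimensionality argument that motivates downsampling applies
with double force to a quadratic search, and reported best bands at 5-nm
multiples are consistent with that choice. Antisymmetry of the
normalized difference under band swap makes the unordered search
lossless.

# Evaluation

For test-set measured values Y and predictions Y-hat:

* `rmse()` - `sqrt(mean((Yhat - Y)^2))`.
* `mape()` - `100 * mean(|Yhat - Y|) / mean(Y)`. Note this normalizes the
  mean absolute error by the *overall mean* of the measured values, not
  per-sample; the name collides with the textbook per-sample MAPE but the
  two differ numerically, so the documentation flags it.
* `rpd()` - `sd(Y) / RMSE`, with the sample (n-1) SD of the measured test
  values. An RMSE of zero is reported as `Inf` with a flag.
* `r_squared()` - primarily the squared Pearson correlation of measured
  vs estimated (affine-invariant, the quantity conventionally quoted with
  calibration scatterplots); the `1 - SSres/SStot` variant is co-reported
  (`r_squared_ss()`) since the two are often conflated.
* `classify_rpd()` - four tiers: Excellent (RPD > 3.5, quantitative use),
  Very Good (2.5-3.5), Good (1.5-2.5, qualitative screening), Fair
  (< 1.5, needs work). Exact boundary values fall into the lower tier,
  following the strict inequalities of the published scheme.

`pca_scores()` (column-centered SVD) summarizes spectral variance
structure; group separation in the PC1/PC2 plane is partial by
construction in the synthetic study, since environment enters through
trait means only.

# The synthetic study generator

No public leaf spectra + trait panel matches this design, so
`generate_dataset()` simulates one. It is a first-class, tested module,
not a fixture: its role is to give every downstream stage data with the
structural features the analysis relies on.

What it emulates:

* **Reflectance shape**: a low VIS shoulder rising through a logistic red
  edge (center 715 nm, width 16 nm) to an NIR plateau (~0.48), declining
  gently through the SWIR; absorption dips as truncated Gaussians
  (compact support at 3 sigma, shifted to zero at the cutoff so the NIR
  plateau is untouched by VIS features): pigments at 430/550/660 nm
  driven by CHL, water at 970/1240/1450/1900 nm driven by LWC, dry-matter
  features at 2100/2300 nm (N), 2350 nm (P, deliberately tiny),
  2170 nm (K).
* **Saturating depths**: dip depth scales as `s/(0.5 + 0.5 s)` in the
  trait relative to a reference value - a Beer-Lambert-like saturation
  that makes two-band indices mildly nonlinear in the trait.
* **Trait structure**: six traits drawn per environment group from a
  multivariate Gaussian with group mean shifts (greenhouse highest CHL
  and N, N-deprived field lowest) and a within-group correlation matrix
  (CHL-N +0.70, CHL-SLA -0.40, LWC-SLA +0.40, LWC-K +0.50, N-P +0.60;
  0.40 rather than 0.45 on the SLA pairs because the larger value makes
  the matrix non-positive-definite). Draws are clipped to physical
  ranges.
* **Nuisance variation**: per-sample structural jitter (VIS baseline sd
  0.006, NIR plateau sd 0.012, red-edge position sd 1.0 nm), per-feature
  absorption-depth jitter (pigments 1%, water 2%, dry matter 3-8%),
  per-scan multiplicative gain (sd 1.2%), band noise (sd 0.0025, elevated
  to 0.012 below 450 nm). These are what make the problem honest: they
  bound the achievable R^2 per trait and penalize two-band indices more
  than whole-spectrum models, which can use redundant bands to cancel
  structured nuisance.

The numeric defaults are the package's own study conditions, chosen once
so that the *qualitative* outcome structure of a real
field-plus-greenhouse panel is reproduced - CHL predicted best
(test R^2 ~0.95-0.97), N next, LWC/K/SLA intermediate, P worst (~0.5,
predictable mostly through its correlation with N); whole-spectrum models
beat the best two-band index for CHL; the best CHL band pair falls in the
VIS/red-edge region while LWC/SLA pairs fall in the SWIR. No quantitative
match to any particular instrument or panel is claimed.

What it does **not** emulate, and what passing tests therefore cannot
show about real data: radiative-transfer physics (no PROSPECT-style
plate model), absolute reflectance magnitudes, instrument artifacts such
as detector-junction steps, scattering/specular effects of leaf surface
structure, genotype pedigree structure, or trait distributions of any
real panel. A model that validates here validates the *software*, not a
spectroscopic protocol.

# Numerical choices and edge cases

* All randomness flows from explicit integer seeds; `run_pipeline()`
  derives stage seeds (simulation, split, CV folds, solver shuffle) from
  one master seed via a fixed counter scheme, so stages can be rerun in
  isolation and whole runs are bit-reproducible.
* `train_test_split()` assigns `round(f * n)` samples to training from a
  seeded permutation; folds differ in size by at most one.
* PLSR caps the candidate latent variables at the fold-wise rank bound
  `min(n - ceiling(n/k) - 1, p)` with a warning; NIPALS stops early if X
  deflates to numerical zero (weight norm < 1e-12).
* A constant response is an error for PLSR (nothing to calibrate) but a
  defined degenerate case for SVR (zero coefficients, mean prediction),
  matching the epsilon-insensitive loss which is exactly zero there.
* Zero-variance predictor columns are an error at standardization time,
  named by column.
* Index values where `R_B1 + R_B2 <= 0` are flagged `NA` with a warning
  rather than silently propagated.
* Boundary RPD values (exactly 3.5, 2.5, 1.5) grade downward.

# Problem sizes

The test suite and the acceptance script run the full study at its
default scale - 150 plants per group x 3 groups x 9 scans (4,050 spectra
of 2,151 bands) - for the end-to-end recovery checks, and much smaller
configurations (8-12 plants per group) for pipeline plumbing and
determinism checks. A full acceptance run takes well under a minute of
compute for data generation plus a few seconds per PLSR fit and ~10 s for
an SVR cross-validation at n = 270.

# Known limitations

* The SVR bias is regularized (bias-as-feature). On standardized data the
  response mean is zero, so the practical difference from an
  unregularized intercept is negligible, but solutions are not expected
  to match libsvm-style solvers to machine precision.
* PLSR assumes a univariate response; multi-trait joint calibration
  (PLS2) is out of scope.
* No derivative spectra, SNV, MSC or continuum-removal preprocessing;
  the calibration design under study uses none.
* The exhaustive search considers two-band normalized differences only;
  three-band or ratio families are out of scope.
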