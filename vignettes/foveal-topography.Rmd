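---
title: "Modelling foveal cone and RPE topography and foveal shape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling foveal cone and RPE topography and foveal shape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foveatopo)
```

This vignette is the package's own account of its models, conventions and
numerical choices: what is assumed, what is tunable, what the synthetic
generators do and do not emulate, and where design decisions were genuinely
open.

## From point sets to densities

All mosaic statistics derive from the Voronoi tessellation of the cell
centers (`mosaic_stats()`). Two conventions matter:

* **Neighbours** are cells sharing a Voronoi *edge of positive length*.
  On cocircular configurations (a square lattice is the extreme case) a
  Delaunay triangulation contains degenerate diagonals whose dual Voronoi
  edge has zero length; excluding them is what makes the square-lattice
  closed form (4 neighbours, ICD = spacing, area = spacing²) hold.
* **Bounded cells** are those whose polygon vertices lie strictly inside a
  region; vertices on the boundary (including polygons clipped at the
  analysis window) count as unbounded.

The inter-cell distance (ICD) of a cell is the mean distance to its
neighbours, and under hexagonal packing implies the local density
`D = 10^6 / (ICD² cos(π/6))` cells/mm² (`icd_to_density()`, exactly
invertible by `density_to_icd()`). This per-cell transform is what turns a
mosaic into a dense set of density observations along the meridian.

**ROI densities.** For bounded-mode ROIs the density denominator is the
*summed Voronoi area of the counted cells*, not the nominal ROI area. On a
perfect lattice every tile has area `1/D`, so this convention reproduces
the true density exactly, whereas dividing the bounded count by the nominal
area systematically loses a one-cell border ring (10–20% for a 50 µm ROI at
foveal cone spacing). The nominal-area variant remains available
(`denominator = "roi_area"`) for comparison with conventions that count
centers. Center-counting ("unbounded") ROIs always use the nominal area.

**Adaptive ROIs** grow the smallest centered square holding a target number
of bounded cells, by bisection on the side length (monotone by polygon
containment). On perfectly symmetric lattices several cells can enter at
exactly the same side length, making an *exact* count unattainable; the
smallest ROI reaching the target is then returned with a warning. Generic
(jittered) mosaics do not trigger this.

**Cones per RPE cell.** Membership of a cone center in an RPE Voronoi
region is equivalent to nearest-RPE-center assignment, which is how it is
computed; exact distance ties are broken toward the lexicographically
smaller RPE center so that counts are deterministic and conserve the total.
Cones whose nearest RPE cell is unbounded are reported as unassigned rather
than dropped.

## Density-profile models

Log10 density `y` versus signed eccentricity `r` (degrees, negative =
nasal) is modelled per participant `s` in two families.

**Asymmetric power law** (`family = "power"`):

$$y = \kappa + k_s + (\pi_n + p_{ns}) \log_{10}(r + \rho_s), \qquad r \ge 0,$$
$$y = \kappa + k_s + (\pi_n - \pi_t + p_{ns} - p_{ts}) \log_{10}(\rho_s)
      + (\pi_t + p_{ts}) \log_{10}(|r| + \rho_s), \qquad r < 0.$$

The offset ρ (degrees) prevents an infinite density estimate at the origin;
the branch construction makes the two sides meet exactly at `r = 0` for
*every* parameter and effect draw (an invariant the tests exercise over
1000 random draws). Base-10 logarithms are used on both sides throughout
the package. A power law's exponents are invariant to that choice; only the
amplitude κ rescales, so κ is reported in log10 cells/mm² units.

**Asymmetric generalized exponential** (`family = "genexp"`):

$$y = \log_{10}(e)\,[\kappa + k_s - (\lambda_n + l_{ns})\, r^{\pi_n + p_{ns}}],
\qquad r \ge 0,$$

with the analogous `λ_t, π_t` branch for `r < 0`. Both branches equal
`log10(e)·(κ + k_s)` at the origin, so the participant's peak density is
`exp(κ + k_s)` on the linear scale — this is what `peak_density()` returns.

**Random effects and positivity.** Every parameter carries an independent
zero-mean Gaussian participant effect (variances only, no covariances).
Parameters that must stay positive — ρ, and the genexp λ and π — are
optimized as natural logs, so their random effects act multiplicatively and
every draw is admissible. The additive-offset-effect variant of the power
model is still available in `eval_power_profile()` (with a domain error
when `ρ + r_s ≤ 0`), but the fitter uses the log-scale parameterization.

**Fitting.** `fit_density_profile()` maximizes the marginal likelihood with
`nlme::nlme` (participant as the nesting variable, diagonal random-effects
covariance). Starting values come from a two-stage initializer that
exploits partial linearity: given ρ the power model is linear in κ, π_n,
π_t (ρ is profiled over a coarse grid), and given the peak the genexp model
linearizes per side as `log(K₀ − y/log10 e) = log λ + π log |r|`. ML is the
default so likelihood-ratio tests between nested fits are valid; REML is
available. Convergence knobs live in `nlme::nlmeControl` (defaults: 200
iterations, tolerance 1e-6); a single automatic retry from a perturbed
start with a damped inner step covers most fragile cases, after which a
diagnostic error is raised.

**Model selection.** `compare_profile_models()` compares fits of the same
observations by AIC (`2k − 2 logLik`), refusing mismatched data via a
fingerprint and reporting exact ties explicitly. AICc is available as an
option but not the default: at the cohort sizes this package targets
(thousands of observations, ~10 parameters) the correction is negligible.
`lr_test()` reports `χ² = 2Δ logLik` with df equal to the difference in
total estimated parameters. For the symmetric-vs-asymmetric power
comparison that difference is 2 here (one fixed exponent + one variance);
published df bookkeeping for such tests varies with which variance
components are tied, so the implementation always reports its own df rather
than assuming a convention. Note also that testing a variance component at
its boundary makes the χ² reference conservative.

## The foveal-shape model

Retinal thickness `t` (mm, ILM to RPE–BrM) at a meridian location is
modelled by `fit_foveal_shape()` (via `lme4::lmer`, ML by default) as

$$t_i = (\beta_0 + b_s) + (\beta_c + b_{c,s}) \log_{10} d_c
      + (\beta_r + b_{r,s}) \log_{10} d_r + \varepsilon_i,$$

where `d_c`, `d_r` are the cone and RPE ICDs (µm) at that location and the
three participant effects are independent Gaussians. No p-values are
reported for the fixed effects — only t-values — because the reference
distribution of these statistics in LMMs is not well defined; term
significance is assessed by likelihood-ratio tests against reduced fits
(`include = "cone"` / `"rpe"`).

**Matching covariates to locations.** `build_shape_observations()` takes
each cone in the meridian strip, evaluates the participant's thickness at
that cone's eccentricity via a cubic-spline interpolant
(`interp_thickness()`, C², no extrapolation — evaluation outside the grid
is an error), and pairs the cone's own ICD with the ICD of the nearest RPE
cell. Folding of nasal and temporal data happens through the absolute
eccentricity at matching time, not inside the regression.

**Variance decomposition.** The question "how much of the
between-individual variance does each term account for?" needs a
convention, and ours is fixed and used identically for generation and
recovery: at observation `i` the between-individual variance is
`σ_b0² + σ_bc² x_c,i² + σ_br² x_r,i²` (with `x = log10 ICD`), each term is
averaged over the observed covariates, the residual variance is added, and
shares are normalized to 100%. A mean-centered alternative was considered
and rejected: because log10 ICDs sit far from zero, slope contributions at
the covariate mean dominate, and no non-negative intercept variance can
realize the canonical split under centering. With 23 participants the three
variance components are correlated in the likelihood; single-replicate
share estimates are noisy (an individual component may collapse to the
boundary), which is why all recovery protocols report shares averaged over
replicate cohorts.

**Per-participant regressions.** `per_participant_regressions()` runs
ordinary least squares of the log10 metric (cone ICD, RPE ICD, or cones per
RPE cell) on thickness per participant and summarizes cohort medians and
IQRs of R². Participants with a constant metric are skipped with a warning.

## Synthetic studies: what they emulate

`population_config()` fixes the study conditions the package is designed
around, chosen once to match a realistic adult cohort:

* 23 participants; ±6° of horizontal eccentricity within a ±0.5° vertical
  strip; 282 µm/degree retinal magnification (a cohort-median foveal
  magnification).
* Cone truth: power law with κ = 4.813 (log10), π_n = −1.0, π_t = −0.9,
  ρ = 0.5°, giving a ~1.3×10⁵ cells/mm² peak falling to ~1.3×10⁴ at 6°;
  participant SDs (0.07, 0.08, 0.08, 0.15 on log ρ) spread peaks over
  roughly 0.9–1.8×10⁵, the range seen in healthy adults.
* RPE truth: generalized exponential with κ = 8.92, λ_n = 0.15,
  λ_t = 0.13, π_n = 0.70, π_t = 0.75 — a ~7.5×10³ peak declining gently to
  ~4.5×10³ at 6°, with participant spread covering ~5.5–11×10³.
* Shape truth: β₀ = 0.006 mm, β_c = 0.291, β_r = 0.064 mm per log10 µm
  (cohort point estimates), residual SD 0.005 mm — small against the
  ~0.15 mm dynamic range of a pit profile. The three random-effect SDs are
  *solved* by `shape_variance_components()` so that the documented
  decomposition convention yields a 46.3 / 40.0 / 12.2 / 1.5 percent split
  (intercept / cone / RPE / residual) on the population profiles; the
  46.3 / 52.2 / 1.5 three-way split is the canonical target, and the
  division of the combined slope share between cone and RPE (not pinned by
  that target) follows the relative coefficient sizes.

`generate_mosaic()` lays a spacing-modulated hexagonal lattice (columns
`s·cos 30°` apart, in-column spacing `s`, alternating half-offsets) whose
local spacing satisfies the packing relation against the requested density
profile, jitters every cell isotropically (SD = 0.12 of local spacing by
default), and enforces a minimum separation of `0.25 s` by redrawing
offending jitters — protecting the tessellation from degenerate slivers
while essentially never triggering at jitter ≤ 0.2 s. Jitter is the single
noise knob: no separate per-cell ICD measurement error is added, so mosaic
ICD noise is geometric, not instrumental.

What the generator does **not** emulate: rod intrusion beyond ~1°, local
mosaic defects and packing dislocations, anisotropic magnification,
detection errors of real cell-marking pipelines, or any joint geometry
between the cone and RPE layers (the two mosaics are generated
independently, since only their densities enter the models). Passing
recovery tests therefore demonstrates correctness of the estimators under
the models' own assumptions, not robustness to real-data artifacts.

Every generator is a pure function of its seed arguments (per-participant
streams are derived deterministically from the master seed), so identical
configs give bit-identical studies, and the pipeline's output tables are
byte-reproducible.

## Recovery protocols and problem sizes

The test suite's cohort-scale protocols use the study conditions above:

* shape-model recovery: one cohort of 23 × 200 locations for fixed
  effects (each within 2 cohort-scale SEs of truth), 50 replicate cohorts
  for the variance shares (means within 5 percentage points of the
  canonical split);
* profile recovery: 25 replicates of 23 × 300 observations per family;
  fixed effects within 3 Monte-Carlo SEs of truth and the AIC selecting
  the generating family in ≥ 90% of replicates;
* geometry, continuity and agreement oracle suites at small fixed sizes.

These sizes keep the full suite at a few minutes on one core while leaving
the Monte-Carlo error well below the tolerances being asserted.

## Numerical choices and edge cases

* Tessellation requires ≥ 4 non-collinear points; duplicate centers are an
  input error.
* Strict containment tests for bounded flags use a relative tolerance of
  1e-7 of the window extent, so polygons clipped exactly at the analysis
  window are classified unbounded regardless of rounding.
* The power-model branch functions evaluate `log10(|r| + ρ)` only, so no
  negative-argument logs arise during optimizer exploration.
* `interp_thickness()` uses the classical C² cubic interpolating spline
  and refuses extrapolation.
* Deming confidence intervals use a seeded nonparametric bootstrap (2000
  resamples by default); degenerate resamples (zero total variance) are
  dropped. Partial correlations define `r = 0` when a variable is
  numerically fully explained by the control.
* The one-way ICC is reported as undefined (NA, with a warning) when the
  between-location mean square is zero.
* All validation errors are raised before fitting: positivity of scales
  and ICDs, minimum participants and observations per participant, both
  eccentricity signs for asymmetric fits.

## Known limitations

* With 23 participants the shape model's three random-effect variances are
  weakly separated; variance shares are meaningful as replicate averages,
  and single-cohort shares should be read with that caveat.
* The nlme-based profile fits occasionally warn about inner-iteration
  convergence on hard draws; estimates at the returned optimum are used,
  and a diagnostic error is raised when the fit genuinely fails.
* Eccentricity is a linear function of retinal position through one scalar
  magnification per participant; individualized schematic-eye optics are
  out of scope.
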