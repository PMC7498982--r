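---
title: "Coarse regional microstructure patterns and post-traumatic amnesia: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse regional microstructure patterns and post-traumatic amnesia: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptapls)
```

## The problem

After severe traumatic brain injury (TBI), the duration of post-traumatic
amnesia (PTA) — the number of days until a patient reliably consolidates
day-to-day memory — is among the strongest clinical indices of injury
severity and prognosis. Diffuse traumatic axonal injury alters white-matter
microstructure in ways that diffusion tensor imaging (DTI) indexes with
high sensitivity: fractional anisotropy (FA) falls and mean diffusivity
(MD) rises in damaged tissue. Because severely injured brains defeat
fine-grained atlas registration, this pipeline deliberately uses a
*coarse* parcellation: five bilateral regions — fronto-temporal (FT),
parieto-occipital (PO), callosal/cingular midsagittal white matter (CC),
brainstem (BS), and basal ganglia plus thalamus (BT). The scientific
hypothesis encoded in the design is centripetal: the deeper the damage
reaches (CC, BS relative to the hemispheric FT, PO and the deep grey BT),
the more severe the injury and the longer the PTA.

## Pipeline overview

1. **Regional extraction** (`extract_regional_metrics`). Region masks are
   eroded by one voxel in all dimensions (full 26-neighbourhood cube), the
   four primarily-white-matter regions (FT, PO, CC, BS) are restricted to
   voxels with FA strictly greater than 0.3 to limit partial-volume
   contamination (BT, being grey matter, is exempt), and voxels inside the
   lesion/microbleed exclusion mask are removed, leaving normal-appearing
   tissue. Means ignore non-finite voxels rather than propagating them.
2. **Age adjustment** (`fit_age_trends`, `apply_age_adjustment`). A linear
   trend of each regional metric on age is estimated in the healthy-control
   group only and subtracted from patient values as
   `value - slope * (age - mean control age)`. FA and MD are adjusted;
   microbleed count and volume are not (they carry no comparable
   healthy-aging trend and the source analysis only standardized them).
3. **Standardization** (`zscore_columns`). Every predictor column and the
   outcome are z-scored across patients (n − 1 SD); the constants are
   retained because held-out rows must be standardized with the training
   fold's constants.
4. **PLS1** (`fit_pls1`). Single-outcome partial least squares by
   sequential X-deflation: each weight vector is the normalized covariance
   between the deflated predictor block and the outcome, so the first
   component is the covariance pattern itself; scores are mutually
   orthogonal; at full rank the fit equals ordinary least squares.
5. **Inference** (`correlate_components`, `permutation_test`). The first
   three component scores are tested against PTA by one-tailed Spearman
   correlation at the Bonferroni-corrected level 0.05/3 ≈ 0.017.
   Predictive value is assessed by leave-one-out cross-validation (LOOCV):
   fold-wise re-standardization, PLS1 on the remaining subjects, held-out
   prediction in standardized units, then the Spearman correlation between
   predictions and truth is referred to an empirical null built by
   re-running the *entire* LOOCV pipeline on B permuted outcome vectors.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| FA threshold | 0.3, strict (`>`) | partial-volume control in WM regions; the boundary voxel is excluded by design |
| Erosion | 1 voxel, 26-neighbourhood | "all dimensions" implies the full cube; border voxels never survive |
| Components | 3 | smallest count whose cumulative predictor variance exceeded 80 % for all four imaging variables in the motivating analysis; `choose_components()` re-derives it from data |
| Corrected alpha | 0.05 / 3 | three components tested per metric |
| Permutations B | 10,000 | resolves p ≈ 0.001 comfortably; the C++ core makes this cheap |
| PTA imputation | 400 days | a patient who dies before emerging from PTA has no observable duration; a constant beyond the observed maximum keeps the rank analysis meaningful and is recorded in provenance |

Two counting rules are available for the permutation p: the default is the
strict fraction of null correlations exceeding the observed one (which can
return exactly 0); an add-one smoothed variant `(1 + #{null ≥ obs})/(1 + B)`
is reported alongside for users who need a positively biased but never-zero
estimate.

## Sign conventions

PLS component signs are arbitrary. The package fixes each component so the
sum of its predictor loadings is ≤ 0 (ties broken by a non-positive first
loading). For FA — where damage lowers the metric — this orients the global
damage component with all-negative loadings, so a *higher* component score
means *more* damage and the one-tailed component tests point in the
positive direction. Pattern-recovery tests compare loadings up to a global
sign, so the convention affects presentation, not substance.

## The synthetic cohort: a stated world

No patient data ship with the package. `generate_cohort()` draws a cohort
whose structure matches the targeted study design: 14 patients and 21
healthy controls, ages uniform on 18–77 years, linear age trends per
region, and two latent per-patient damage severities — global `g` and
deep-vs-superficial `d`, independent standard normals — expressed through
two unit-norm spatial patterns (global: same sign in all five regions;
deep: CC and BS opposite to FT, PO, BT). Regional metrics are

```
value = baseline_r + slope_r * age + e_g * g * global_r + e_d * d * deep_r + noise
```

and PTA is linear in `(g, d)` with intercept 190 days, 80 and 60 days per
SD of global and deep severity, residual SD 60 days, clipped to 0–450 days
and rounded. Controls have `g = d = 0` and no PTA. The generator retains
its ground truth (severities, patterns, noiseless means), and regenerating
with noise switched off reproduces the stored noiseless structure exactly.

The published analysis reports no effect sizes for its latent patterns, so
the defaults are this package's choice, made once: FA effects of −0.08 and
−0.06 FA-units per SD of severity against a residual SD of 0.008 (other
metrics scaled to the same signal-to-noise ratios). These values were
calibrated so that the planted structure is recoverable at n = 14 in a
clear majority of seeds — component 1 uniformly signed and component 2
showing the deep/superficial split in roughly 70–80 % of seeds, permutation
p < 0.05 in roughly 85 % — because a default world in which the pipeline
usually fails on its own design size would make every downstream check
uninformative. They are *not* claimed to be the study's effect sizes.

What the generator does **not** emulate: realistic brain geometry (the
volume generator paints axis-aligned blocks), spatial noise correlation,
non-linear aging, heteroscedastic outcome noise, or correlated severities.
A green recovery test therefore establishes that the pipeline recovers the
structure it assumes, on data that satisfy its assumptions — nothing more.

## Numerical choices

- **Erosion before thresholding before exclusion.** Threshold and
  exclusion commute; erosion does not, so the order is fixed and recorded.
- **Nearest-label assignment** uses physical distances (`voxel_size`),
  supports anisotropic voxels, and breaks exact ties toward the lowest
  label id so results are independent of scan order.
- **Standardization checks**: `fit_pls1` refuses non-standardized input
  (tolerances 1e−6 on means, 1e−4 on SDs) rather than silently
  re-standardizing, because fold-wise constants are the caller's
  responsibility in LOOCV.
- **Rank**: requesting more components than `rank(X)` is an error; inside
  a fold the C++ core stops when the residual covariance vanishes.
- **Determinism**: all randomness flows from explicit integer seeds; the
  generator draws sub-streams in a fixed order (ages, severities, metric
  noise in declared metric order, PTA noise) so adding a metric never
  perturbs the preceding draws.
- **Dual implementation**: the permutation loop is compiled
  (RcppArmadillo) for speed; the R path (`loocv_predict(engine = "r")`)
  is the readable reference and the test suite holds the two to 1e−10
  agreement, with an independent Krylov-subspace PLS oracle as a third
  route.

## Limitations

- At n = 14 the LOOCV correlation is a noisy statistic; the permutation
  null is the honest way to calibrate it, and even then a single cohort's
  p-value has Monte-Carlo resolution 1/B.
- The t-approximation for Spearman p-values is approximate at these sample
  sizes; the component tests should be read as ranking evidence, not exact
  tail probabilities.
- Slope-only age adjustment and full residualization differ by a
  per-column constant that z-scoring removes; both are provided, and the
  choice is immaterial to every downstream statistic.
- The NIfTI layer reads and writes plain single-frame NIfTI-1 volumes and
  interprets only voxel size; inputs are assumed co-registered, and no
  reorientation is attempted.
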