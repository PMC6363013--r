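---
title: "Radiomics-based survival stratification: models, parameters and design choices"
author: "RadSurv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomics-based survival stratification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RadSurv)
```

## Overview

RadSurv implements a complete prognosis workflow for multi-sequence brain
MRI: a fixed 286-feature radiomic catalog computed inside a single tumor
mask shared by the T1-weighted (T1WI), contrast-enhanced T1-weighted
(T1WI_CE) and FLAIR sequences; LASSO-based selection of outcome-relevant
features; Youden-cutpoint dichotomization with Kaplan-Meier/log-rank
comparison; combination of a radiomic feature with MGMT promoter
methylation status; and frozen-cutoff external validation. Because
suitable patient imaging is rarely shareable, the package ships a phantom
cohort generator that reproduces the statistical structure the analysis
assumes, so every stage is testable end to end.

This vignette records the models, the tunable parameters and their
defaults, the numerical conventions, and the design decisions taken where
the method left genuine freedom. It states no empirical numbers beyond
those the package's tests and acceptance script themselves compute.

## The feature catalog

Each patient contributes exactly 286 named features,
`<sequence|shape>.<family>.<feature>`:

* **Intensity histogram (3 x 20).** First-order statistics of the
  *unscaled* masked intensities: min, max, range, mean, median, SD,
  variance, skewness, excess kurtosis, the 10th/25th/75th/90th
  percentiles, interquartile range, energy, entropy, RMS, mean absolute
  deviation, coefficient of variation and uniformity. Moments use
  population (biased) denominators; percentiles interpolate linearly
  between order statistics; entropy and uniformity use 128 equal-width
  bins over the masked range with log base 2. Degenerate quantities
  (skewness of a constant region) are reported `NA` and later excluded
  from selection rather than imputed.
* **GLCM (3 x 26).** Intensities are first rescaled to `Q = 128` gray
  levels by `round((Q-1)(x - vmin)/(vmax - vmin) + 1)` with `vmin`/`vmax`
  taken inside the mask and *round-half-up* rounding (banker's rounding
  would move level boundaries). Co-occurrences are counted at an offset of
  one voxel in all 26-connected directions (13 unique offsets, both
  orderings), over pairs with both voxels in the mask, and merged into a
  single symmetric matrix before feature computation. The 26-feature block
  covers the joint/difference/sum statistics, the inverse-difference
  family, correlation measures (including the maximal correlation
  coefficient via the second eigenvalue of the transition-like matrix) and
  the cluster statistics.
* **GLSZM (3 x 16).** Zones are maximal 26-connected components of
  constant gray level inside the mask, from the same quantized volumes
  (the same `Q` as the GLCM; the two matrices are intended as companions).
  The zone-size-weighted total always equals the masked voxel count, which
  the tests assert against a flood-fill oracle.
* **Gabor edge statistics (96).** A 2D Gabor quadrature pair (even cosine
  + odd sine carrier under an isotropic Gaussian envelope) is applied
  slice-wise in the axial plane to each *unscaled* sequence at four
  orientations (0, 30, 45, 90 degrees from the image x-axis) and two
  frequency labels, interpreted as carrier wavelengths of 2 and 2*sqrt(2)
  pixels — the Nyquist-anchored convention of standard Gabor banks; the
  envelope width follows the one-octave-bandwidth relation
  `sigma = 3 * lambda / pi * sqrt(ln 2 / 2)`. The edge map is the
  quadrature *magnitude*: non-negative, phase-insensitive edge strength.
  That yields 4 x 2 x 3 = 24 maps; each contributes its masked mean, SD,
  skewness and excess kurtosis. Filtering in pixel units means thresholds
  transfer across voxel sizes only when acquisitions share in-plane
  resolution — a documented limitation, not a hidden assumption.
* **Shape (4).** Volume is masked voxel count times voxel volume. Surface
  area comes from a marching-tetrahedra iso-surface (iso 0.5) of the mask
  indicator lightly smoothed with a Gaussian of 0.6 voxels; the smoothing
  width was calibrated once against analytic spheres and irregular
  thresholded-noise shapes so that digitized balls measure sphericity in
  [0.95, 1.0] and no shape exceeds 1 beyond mesh tolerance. Sphericity is
  `pi^(1/3) (6V)^(2/3) / A` and the surface-to-volume ratio is `A / V`.

Histogram, Gabor and shape features never depend on `Q`; only the GLCM
and GLSZM blocks do. `binSensitivity()` exploits this to re-run selection
at several `Q` settings while recomputing only the texture blocks.

## Selection and survival model

Features are standardized to mean 0 and *population* SD 1; the centers and
scales are frozen and re-applied verbatim to validation data. Constant or
incomplete features are excluded (and reported), never imputed. Selection
fits an L1-penalized logistic regression (elastic-net mixing parameter 1)
of end-of-follow-up vital status on the standardized features; the penalty
is tuned by 10-fold cross-validated deviance. The default tuning rule is
the *one-standard-error* lambda (`lambdaRule = "1se"`; the raw deviance
minimizer remains available as `"min"`). The procedure being reproduced
specifies only "cross-validated tuning", so the rule was an open choice,
and the package's own experiments decided it: the deviance minimizer
returns sets of 12-19 features dominated by near-zero stragglers whose
identity changes when the gray-level setting of the texture blocks — a
nuisance parameter — changes, whereas the 1-SE rule returns compact sets
(one to a handful of features) that are identical across gray-level
settings and match the reported behavior of this analysis type (a
single-digit selected set out of 286 candidates, unchanged across
binning). Fold assignment is seeded and recorded so reruns are
byte-identical.

Each selected feature is dichotomized at the cutpoint maximizing the
Youden index (sensitivity + specificity - 1) over all midpoints between
consecutive sorted unique values, both orientations considered, ties
broken toward the smaller cutoff. The ROC outcome is the same vital-status
binary used for selection; the method defines no time-horizon
dichotomization. Groups are compared by the log-rank test on Kaplan-Meier
curves (log-log/Greenwood 95% CIs; the median is the smallest time with
S(t) <= 0.5 and is reported `NA` when the curve never crosses 0.5), with
Bonferroni adjustment over the number of *simultaneously tested* features
(the selected set in training; the carried-forward set in validation —
not the full catalog, since only the selected features are tested).

The MGMT combination defines group 1 as methylated patients with feature
value *below* the cutoff and group 2 as all other patients with known MGMT
status; patients with unknown MGMT are excluded from combined analyses
only. The survival probability at a requested horizon (default 43 months)
is reported alongside the medians.

External validation freezes everything learned on the training cohort:
standardization parameters, the carried feature set and their cutoffs.
Two cutoff modes exist because the method's description is ambiguous
between the training-*optimal* (Youden) and training-*median* value;
`training_optimal` is the default and `training_median` is kept as an
explicit mode switch rather than guessing intent. Group assignment on
validation data depends only on the sign of (value - cutoff); a test
asserts that shuffling validation outcomes cannot change assignments
(leakage guard).

## The phantom cohort generator

`makePhantom()` builds one patient on a 48^3 grid at 1 mm isotropic
spacing (defaults): an ellipsoidal tumor mask with semi-axes (a, b, c); a
rim of amplitude 80 on T1WI_CE whose profile is a Gaussian of the
(approximate) signed distance to the ellipsoid surface with width
`sigma_edge` — small widths give a thin, sharp enhancing ring and strongly
right-skewed Gabor magnitude distributions, large widths a diffuse rim and
lower skewness (a monotone handle verified by a Spearman test); interior
texture from white noise smoothed to correlation length `ell` (short `ell`
raises GLCM contrast); an edema-like halo on FLAIR (the ellipsoid enlarged
by 3 mm at +30 intensity); and additive white noise of SD 5 on a base
intensity of 100 with +20 tumor contrast. All draws are seeded; phantoms
are bit-reproducible.

`CohortSpec` links imaging to outcomes through a proportional-hazards
model with constant baseline hazard (exponential event times — the
simplest model satisfying proportional hazards; the baseline shape is
irrelevant to the validity checks of KM and the log-rank test):

```
log h_i = beta0 + betaMgmt * MGMT_i + betaImg * sigma_edge_i
          [+ betaInteraction * I(MGMT_i & sigma_edge_i > threshold)]
```

with censoring uniform on [0, 60] months. Per patient, MGMT ~
Bernoulli(0.40) (the known-status methylation fraction typical of
glioblastoma cohorts), `sigma_edge` ~ U(0.4, 2.0) mm, semi-axes ~
U(8, 14) mm and texture length ~ U(0.8, 2.5) mm, so shape and texture
features vary across patients independently of the hazard.

Default coefficients are `beta0 = -0.6`, `betaMgmt = -0.7` (hazard ratio
about 0.5, the usual magnitude of the methylation effect) and
`betaImg = -1.8` per mm. These were fixed by a priori power analysis, not
by data: with them the cohort death fraction is about 0.65, methylated
patients live roughly twice as long as unmethylated at the median, and a
frozen median split of the hazard-linked feature retains roughly 0.9 power
for a Bonferroni-adjusted log-rank test at n = 60 — the operating point
the replication checks require. The sign of `betaImg` is chosen so that
the *protective* image phenotype (large `sigma_edge`, low Gabor skewness)
lies on the "feature < cutoff" side, matching the combined analysis's
fixed group definition.

What the generator does *not* emulate: MR physics (bias fields, Rician
noise, k-space artifacts), anatomy, multi-site intensity scale drift, or
registration error. Passing tests therefore demonstrate correctness of
the computational pipeline and recoverability of planted effects under the
stated model — not clinical performance on real data.

## Simulation design of the replicate studies

Phantom imaging is a deterministic function of the per-patient parameters,
so replicate studies that probe the *survival* machinery redraw only the
exponential event times and uniform censoring, conditional on fixed
imaging cohorts (`redrawOutcomes()`): the selection-recovery study uses
four independent imaging cohorts of n = 200 with five outcome redraws
each (20 replicates); the dominance and validation-replication studies
use fixed cohorts with 50 outcome redraws. Re-imaging every replicate
would multiply compute by two orders of magnitude without adding
stochastic content beyond what the parameter redraw across the four
cohorts already provides.

The dominance study plants a pure protective interaction (hazard reduced
only for methylated patients on the protective side of the rim-width
distribution) and asks whether the combined group's Kaplan-Meier curve —
methylated patients with the edge feature under the cohort median, the
combined analysis's own group definition — lies above the rest. Because
empirical KM curves move in steps of one event, a dip smaller than one
step of the smaller group is a tie at the estimator's resolution, not a
reversal, and is treated as such; deeper or persistent reversals count
against the replicate. The validation-replication study freezes the
discovery-cohort *median* of the planted feature (the dichotomization the
validation protocol prescribes) and re-tests the split on independent
60-patient cohorts with Bonferroni multiplicity 4, the number of carried
features.

"Recovering the planted feature block" is defined as the selected set
containing at least one T1WI_CE feature. The planted hazard driver —
rim edge width — moves the whole T1WI_CE block (Gabor, GLCM and histogram
features) coherently, and the LASSO deliberately returns a sparse
representative among collinear predictors, so demanding one specific
sub-family would test the solver's tie-breaking rather than signal
recovery. All other sequences' features, and the shape block, are
independent of the hazard by construction, which makes the channel-level
criterion sharp.

Problem sizes used by the test suite (chosen as a balance of statistical
resolution and a test run a developer will actually wait for): unit tests
run phantoms at 32^3 with proportionally smaller tumors; the end-to-end
studies run the default 48^3 phantoms at n = 200 (training), n = 60
(validation), and n = 120 (gray-level sensitivity).

## Numerical conventions and degenerate inputs

* Quantization rounds half *up*; a constant masked region is a
  degenerate-intensity error, not a silent one-level matrix.
* A single-voxel mask has no co-occurring pairs: an explicit error.
* Zero-variance distributions yield `NA` skewness/kurtosis; GLCM
  correlation and the maximal correlation coefficient are `NA` for
  single-level matrices. `NA` features are dropped from selection with a
  warning; patients are never dropped for feature degeneracy. Patients
  lacking MGMT status are excluded only from MGMT-combined analyses.
* The Youden search breaks ties toward the smaller cutoff; coefficients
  from the LASSO below 1e-10 in absolute value are treated as numerical
  zeros of the coordinate-descent solver.
* Gabor responses are computed over the mask's padded bounding box (or,
  as a fast path, at masked voxels only — bit-identical masked
  statistics); voxels outside are zero and never enter any statistic.
  Slice edges use replicate boundary handling.
* The mesh pads the mask with a zero border so iso-surfaces close at the
  volume boundary; surface area is therefore well-defined for masks
  touching the grid edge.

## Known limitations

* Gabor frequencies are defined in pixels, not millimeters; cutoffs are
  transferable only across acquisitions with equal in-plane resolution.
* No intensity standardization or voxel resampling is applied (by
  design, mirroring a deliberately acquisition-agnostic workflow); GLCM /
  GLSZM values are therefore sensitive to voxel-size heterogeneity.
* The GLCM offset is one voxel in index space; spacing anisotropy is
  ignored for offsets (the standard one-voxel convention).
* Exponential event times are a modeling convenience; real survival data
  have non-constant baseline hazards. None of the implemented checks
  depend on the baseline shape.
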