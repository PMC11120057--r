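---
title: "Autonomous tumor-signature extraction and SCR scoring: methods"
author: "bpscr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autonomous tumor-signature extraction and SCR scoring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpscr)
```

## The problem

Prostate tumors on bi-parametric MRI are hypointense on the apparent
diffusion coefficient map (ADC), hyperintense on the high b-value image
(HBV) and hypointense on T2-weighted images. When the three sequences are
registered voxel by voxel, every voxel carries a 3-vector spectrum, and a
tumor is a spectral anomaly against the normal-prostate background — the
multispectral target-detection setting familiar from remote sensing.
`bpscr` implements a fully autonomous version of that analysis: it finds a
candidate tumor voxel on its own, extracts the spectral signature there,
and converts it into a per-patient scalar that can be fitted against
pathology (ISUP grade group) and clinical significance (CsPCa, defined as
ISUP ≥ 2).

## Pipeline

1. **Registration** (`assemble_hypercube`): the three sequences are
   resampled (bilinear in-plane, nearest-neighbour across slices) onto the
   grid of the channel with the coarsest in-plane resolution — in practice
   the ADC/HBV grid — and translated by the rounded origin-offset
   difference. No deformable registration is attempted; the manual
   fine-tuning that a human operator might apply is exposed as an optional
   integer `(dy, dx)` shift.
2. **Green image** (`stretch_hypercube`, `green_ratio`): each channel is
   stretched over prostate voxels so its 1st percentile maps to 0 and its
   98th to 1 (aberrant voxels clip to 0/1), and the normalized green ratio
   `g = HBV' / (ADC' + HBV' + T2')` is formed. With (R, G, B) = (ADC, HBV,
   T2), tumors are the greenest voxels.
3. **Blob detection** (`detect_blobs`): threshold `g ≥ 0.90`, clean with a
   per-slice 2×2 erosion followed by a 3×3 dilation, label 8-connected
   components within each slice, and drop blobs below 12 voxels.
4. **Blob selection** (`rank_blobs`): blobs are rated relative to one
   another on eight criteria — size, mean green, best 3×3 sliding-window
   mean, best window covariance (mean/std), standard deviation,
   eccentricity, position, blob covariance — with weights
   1, 2, 3, 3, 1, 0, 1, 2. Rank sums decide; the minimal-score blob wins.
5. **Signature** (`signature_variants`): the winning blob contributes a
   single raw (un-stretched) 3-vector, taken either at its center of mass
   (`Signature CM`) or at the center of its best sliding window
   (`Signature Green`); averaging over all blobs gives the `Ave Blob`
   variants.
6. **Scoring** (`scr`, `zscore`): the signal-to-clutter ratio is the
   whitened Euclidean distance
   `SCR = sqrt((s − μ)ᵀ CM⁻¹ (s − μ))`
   between the signature `s` and the normal-prostate mean `μ` under a
   background covariance `CM`; the z-score is the same distance with
   `CM = diag(σ²)`, ignoring inter-sequence correlation.
7. **Evaluation** (`evaluate_scores`): per covariance treatment and
   signature mode, scores are fitted linearly to ISUP (Pearson R, two-sided
   p from the t statistic) and logistically to CsPCa, with the ROC AUC
   resampled over 1000 random 70/30 train/test splits; the 2.5/97.5
   percentiles of the split AUCs form the 95% confidence interval. Because
   a univariate logistic fit is monotone in its input, each split's test
   AUC equals the raw-score AUC of that test set; the resampling therefore
   measures sampling variability, not model capacity.

## Covariance treatments

The sample covariance of the masked voxels is conditioned in five ways
before inversion (plus the diagonal z-score matrix):

* **UNTRANSFORMED** — the population (divide-by-n) covariance as is.
* **PC_FILTER** — eigenpairs with `λ < 0.01·λmax` are discarded; the
  whitening inverse is the pseudo-inverse over the kept components.
* **REG** — shrinkage `CM(γ) = (1−γ)CM + γ(tr(CM)/3)I`. The trace-scaled
  identity keeps the target in the data's own units, so γ is comparable
  across patients.
* **MOD_REG** — the same mixture with the diagonal of CM (the channel
  variances) as target, so only the off-diagonal correlation structure is
  shrunk.
* **ELLIPTIC** — elliptical volume minimization: 200 seeded trials each
  drop a random 10% of the voxels; the retained set with the smallest
  covariance determinant (smallest ellipsoid volume) supplies both mean
  and covariance. Voxel rows are sorted canonically before subsampling, so
  the estimate does not depend on input order. Random 10%-deletion is a
  mild robustifier: with 10% planted outliers its best trial removes only
  a minority of them, so the volume shrinks moderately rather than
  collapsing to the inlier ellipsoid.
* **ZSCORE_DIAG** — `diag(σ²)`; `zscore()` is algebraically identical to
  `scr()` with this matrix.

The shrinkage parameter γ is chosen on a grid (0 to 1 in steps of 0.05) by
5-fold held-out Gaussian likelihood: each fold scores
`−[ln det CM(γ) + dᵀCM(γ)⁻¹d]` averaged over held-out deviations `d` from
the training mean, and the γ with the best average wins (ties to the
smallest γ). For the 3-dimensional, many-thousand-voxel case the selected
γ is usually 0 or very small; the machinery matters for small masks.

## Numerical conventions

* Percentiles interpolate linearly between order statistics
  (`quantile type 7`).
* All variances and covariances use the population (divide-by-n)
  convention, so `diag(cov) = σ²` exactly and the z-score/SCR identity is
  exact.
* Ratios mean/std use an ε floor of `1e−6` when a blob or window is
  constant; such records carry a flag.
* Window-best ties break by larger mean, then smaller row, then smaller
  column; rank-sum ties break by larger size, larger mean green, lowest
  blob id. Labeling order is raster order (slice, then top-left first), so
  every result is deterministic.
* The threshold comparison is `≥` (0.90 itself passes).
* 3×3 matrix inversion goes through `solve()` on the linear system, never
  an explicit inverse; a matrix whose smallest eigenvalue is below
  `1e−12·λmax` flags the patient rather than producing a number.

## Detection green versus statistics green

A raw green ratio rarely exceeds 0.9 (it requires `ADC' + T2' < HBV'/9`),
so the fixed 0.90 threshold is interpreted against a per-patient re-stretch
of the green image (the same 1/98 percentile rule); the raw-ratio
alternative is available via `rescale_green = FALSE`. The re-stretch,
however, clips everything beyond the patient's 98th green percentile to
exactly 1.0. Inside any strong candidate that saturates a whole 3×3
window, the window standard deviation would be exactly zero, every such
window would tie through the ε rule, and the tie-break — not the data —
would pick the signature voxel. Blob and sliding-window statistics are
therefore computed on the un-re-stretched quantitative ratio, which
preserves the within-blob ordering, while thresholding uses the
re-stretched image. `detect_blobs(green, stats_green = ...)` exposes the
split.

## The synthetic phantom

`make_phantom` builds the cohort the tests and the acceptance script run
on. Its design goal is that the planted truth is recoverable by the
pipeline under realistic conditions, so that end-to-end failures indicate
bugs rather than modelling accidents.

* **Geometry**: an ellipsoidal prostate of ≈ 13,500 voxels at
  (3, 1, 1) mm spacing (≈ 40 cm³, a typical gland) inside a
  16 × 64 × 64 volume.
* **Background**: 3-channel Gaussian noise at ADC 1200 ± 250
  (10⁻⁶ mm²/s), HBV 120 ± 30 (a.u.), T2 400 ± 90 (a.u.) — plausible
  magnitudes chosen to exercise unit heterogeneity in the covariance, not
  claims about any scanner. Channel correlation is positive
  (ADC–T2 0.65, HBV–T2 0.50, ADC–HBV 0.25): normal-gland contrast is
  dominated by tissue composition, which moves the three sequences
  together. The tumor pattern (ADC↓, HBV↑, T2↓) runs against that common
  mode — which is precisely why whitening by the background covariance
  can amplify it relative to the plain z-score. Noise is a mixture of a
  spatially coherent component (40% of variance, 0.8-voxel in-plane
  correlation length) and voxelwise thermal noise; the coherent scale is
  deliberately below the 12-voxel blob-size floor so pure-noise structures
  are mostly removed by morphology and the size filter.
* **Lesion**: one ellipsoid per patient with grade > 0, with per-channel
  mean shift `grade × (−0.8, +0.8, −0.6) × σ`, radii growing 8% per grade
  step (higher-grade tumors are larger), edges blurred for partial volume,
  and a smooth multiplicative contrast modulation (sd 0.4) emulating
  tumor heterogeneity — the feature the sliding-window search exists for.
* **Benign mimics**: every patient carries three homogeneous,
  well-circumscribed BPH-like nodules with the tumor's channel polarity at
  0.7–1.2 grade-equivalents — below clinically significant contrast.
  Without them no normal gland would ever produce a candidate blob, the
  clinically insignificant class would be silently dropped, and the CsPCa
  comparison would be vacuous. Their amplitude overlaps grade-1 disease by
  design: that is the clinical reality that makes the grade-2 boundary
  hard.
* **Cohort**: 42 patients with grade multiset
  {0:14, 1:10, 2:8, 3:5, 4:3, 5:2} (mean ≈ 1.17, near the study
  population's 1.12), per-patient seeds derived from one master seed.

What the phantom does **not** model: Rician noise (channels are treated as
roughly normal; a distribution-agnostic pipeline gains nothing from the
exact noise law at these SNRs), zonal anatomy, bias fields, scanner
harmonization, registration error beyond integer translation, and
multifocal carcinoma. Passing the recovery tests therefore shows the
pipeline implements its contract, not that it would reach the same
operating point on clinical data.

### What recovery the phantom supports

With the defaults above, the dominant residual confound is intrinsic: a
grade-2 lesion sits ≈ 1 grade-equivalent above the benign mimics any
scored negative class must carry, while single-voxel signature extraction
adds max-statistics selection noise. Across master seeds the cohort-level
Pearson R between the MOD_REG SCR (greenest-window signature) and planted
grade is typically in the low 0.8s, and the median resampled CsPCa AUC is
typically around 0.9, clearing 0.95 only on favorable seeds. The test
suite asserts the stricter recovery targets unchanged at the package's
default seed and documents the outcome; the acceptance script reports the
measured values for whatever seed it is given.

## Problem sizes

The test suite runs phantoms at the default 16 × 64 × 64 geometry, 20
seeds for single-lesion localization, one full 42-patient cohort for the
cohort-level check, and a 10-patient cohort twice for bit-reproducibility;
the resampled confidence intervals use 1000 splits in the cohort check and
100–400 where only determinism or coverage is at stake. The acceptance
script runs the full 42-patient pipeline with all six covariance
treatments and 1000-split intervals (about a minute on one CPU).

## Known limitations

* The center-of-mass voxel can fall outside a strongly curved blob; the
  nearest-blob-voxel fallback is deterministic but may sit at the blob's
  edge.
* Sliding windows may extend outside their blob (but never outside the
  prostate); this follows the reading that the window characterizes the
  local neighbourhood, not blob membership.
* The random-deletion elliptical-volume minimizer is a weak robustifier
  (see above); it is kept because it is the procedure the pipeline
  specifies, not because it is the best available robust estimator.
* DICOM support covers uncompressed explicit/implicit little-endian
  single-frame series with consistent orientation — enough for exported
  research series; compressed syntaxes and multi-frame objects are
  rejected loudly.
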