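# bpscr

Autonomous tumor-signature extraction and signal-to-clutter scoring for
spatially registered bi-parametric prostate MRI.

## What this package is for

On bi-parametric MRI (ADC, high b-value, T2-weighted), prostate
carcinoma shows a characteristic spectral pattern: low ADC, high HBV, low
T2. Once the three sequences are registered at the voxel level, each voxel
carries a 3-vector spectrum, and a tumor can be treated as a spectral
anomaly against the normal-prostate background — the detection problem of
multispectral remote sensing transplanted into the pelvis. Existing
spectral/statistical pipelines for this setting require a human to click
a tumor-like voxel; `bpscr` removes the human: it builds a normalized
"green" ratio image in which tumor spectra stand out, detects candidate
blobs, ranks them, picks a signature voxel autonomously, and converts the
signature into a per-patient scalar score whose relationship to pathology
can be evaluated. The intended users are imaging researchers working with
registered bi-parametric data (e.g. the public PI-CAI collection) or with
synthetic phantoms.

The score is the **signal-to-clutter ratio**, a whitened Euclidean
(Mahalanobis-type) distance

```
SCR = sqrt( (s − μ)ᵀ CM⁻¹ (s − μ) )
```

between the tumor signature `s` (a raw 3-vector at the chosen voxel) and
the normal-prostate mean `μ`, under a background covariance `CM` that can
be used untransformed, PC-filtered, shrinkage-regularized toward an
identity or diagonal target, estimated robustly by elliptical volume
minimization, or replaced by `diag(σ²)` — the last variant being exactly
the per-channel **z-score** `sqrt(Σ((s_k − μ_k)/σ_k)²)`. Scores are fitted
linearly to ISUP grade (Pearson R, p) and logistically to clinically
significant cancer (ISUP ≥ 2), with ROC AUC confidence intervals from
1000 random 70/30 train/test splits.

A seeded synthetic-phantom generator (`make_phantom`, `make_cohort`)
produces registered hypercubes with planted lesions whose contrast scales
with grade, benign tumor-mimicking nodules, and correlated background
noise, so the entire pipeline is testable without patient data.

## Worked example

```r
library(bpscr)

ph  <- make_phantom(grade = 4, seed = 43)        # one synthetic patient
ext <- extract_patient(ph$cube, ph$mask)         # green image -> blobs -> signatures

blob_table(ext$blobs, "P042")[, c("blob_id", "slice", "size",
                                  "mean_green", "blob_cov", "position_score")]
#>   blob_id slice size mean_green blob_cov position_score
#> 1       1     5   65      0.758     3.07          13.46
#> 2       2     6   75      0.703     3.27          11.30
#> 3       3     7   55      0.736     3.57           9.39

sig <- ext$signatures[["Signature Green"]]       # greenest-window voxel
round(sig$s, 1)
#>   ADC   HBV    T2
#> 162.1 217.4 239.8
```

The planted grade-4 lesion spans slices 5–7 and is detected as three
per-slice blobs; blob 3 wins the weighted ranking (best blob covariance
and position). The signature voxel's ADC is far below and its HBV far
above the background (1200 ± 250 and 120 ± 30 respectively), as a dense
tumor should be. Scoring it against the six background treatments:

```r
bg <- background_variants(ph$cube, ph$mask, seed = 7)
for (m in names(bg$covs)) {
  st <- if (m == "ELLIPTIC") bg$evm_stats else bg$stats
  s  <- if (m == "ZSCORE_DIAG") zscore(sig, st) else scr(sig, st, bg$covs[[m]])
  cat(sprintf("%-13s %.3f\n", m, s))
}
#> UNTRANSFORMED 5.364
#> ELLIPTIC      5.422
#> PC_FILTER     5.364
#> REG           5.364
#> MOD_REG       5.364
#> ZSCORE_DIAG   5.213
```

An SCR of ~5.4 says the signature sits over five whitened standard
deviations from normal prostate. A full cohort run — simulate, extract,
score, evaluate — is one call:

```r
res <- run_pipeline(n = 42, seed = 1)
res$report   # one row per covariance treatment x signature mode:
             # Pearson R, p, AUC (median of 1000 splits), 95% CI
```

The same workflow is available from the shell via the bundled entry point
(`inst/cli/bpscr`): `simulate`, `extract`, `score`, `evaluate`, `run-all`
subcommands with a YAML config mirroring `default_config()`.

## Package layout

- `R/hypercube.R`, `R/dicom.R` — registration and NIfTI/DICOM input
- `R/green.R`, `R/blobs.R`, `R/select.R` — green image, blob detection,
  weighted selection, signatures
- `R/background.R`, `R/scores.R` — covariance conditioning, SCR/z-score
- `R/evaluation.R` — fits, ROC/AUC, resampled confidence intervals
- `R/phantom.R` — synthetic cohort generator
- `R/pipeline.R`, `R/cli.R` — orchestration and the command-line workflow
- `vignettes/bpscr-methods.Rmd` — the model, conventions, phantom design
  and limitations in detail
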