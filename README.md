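# relaxseg

Joint segmentation and classification of brain MR images in the 3D
space of estimated proton density and relaxation times (ρ, T1, T2),
instead of on gray-level intensities.

## What it does

Brain segmentation for volumetry, lesion quantification or surgical
planning is usually a thresholding problem on one weighted image.
relaxseg targets users with multi-contrast spin-echo data: it first
estimates the physical parameters behind the contrast, then classifies
each voxel as a point in (ρ, T1, T2) space, where tissue classes are
farther apart and the decision regions follow from estimator
statistics rather than hand tuning.

The pipeline:

1. **Forward model / simulation** — complex spin-echo signal
   `ρ·exp(−TE/T2)·(1−exp(−TR/T1))·e^{iφ}` plus circular Gaussian
   noise calibrated to a target mean SNR (dB).
2. **Relaxometry** — per-voxel least squares over the M complex
   images, with phase and proton density concentrated out in closed
   form and a compiled grid + Nelder–Mead search over (T1, T2).
3. **Estimator covariance** — analytic Fisher information and the
   Cramér–Rao lower bound (CRLB) as the per-class covariance of
   (ρ̂, T1̂, T2̂); ρ̂ and T2̂ come out strongly negatively correlated
   (≈ −0.9 for white matter under the reference protocol at 30 dB).
4. **Classification** — four criteria of increasing statistical
   sophistication plus a baseline:
   * `classify_euclidean` — minimum Euclidean distance to centroids;
   * `classify_wdc` — inverse-variance weighted distance (independent
     Gaussians), with an optional ρ-variance inflation λ for
     bias-field robustness;
   * `classify_stcc` — full-covariance Mahalanobis distance
     `(x̂−μₙ)ᵀ Σₙ⁻¹ (x̂−μₙ)` exploiting the estimator correlation;
   * `spcc_refine` — spatial refinement: each voxel re-minimizes
     `dₙ − p(n)·d₀` where p(n) is the fraction of its 8-neighbors
     labeled n and d₀ its minimal StCC distance;
   * `kmeans_baseline` — Lloyd's K-means on a scalar composite image,
     the single-image reference method.
5. **Evaluation** — confusion matrix, per-class Dice, Jaccard,
   detection and false-alarm probabilities against a ground-truth
   phantom; cluster alignment by overlap-maximizing permutation.

A procedural four-tissue brain phantom (WM, subcortical WM, GM, CSF
with 3 T literature parameters), 20%-style multiplicative bias fields
and NIfTI + JSON import/export support end-to-end studies; the same
code path handles real acquisitions.

## Worked example

```r
library(relaxseg)

res <- run_phantom_study(snr_db = 30, seed = 1)
round(sapply(res$reports, function(r) r$overall_accuracy), 4)
#> euclidean       wdc      stcc      spcc    kmeans
#>    0.8073    0.9231    0.9994    1.0000    0.5304
```

One seed of the reference study: 160×160 four-tissue phantom, four
images at (TE, TR) = (80, 3600), (80, 500), (155, 3600), (155, 500) ms,
mean SNR 30 dB. Overall accuracy climbs as the criteria exploit more
of the estimator statistics — Euclidean distance misassigns ~19% of
voxels, variance weighting (WDC) cuts that to ~8%, the full covariance
(StCC) to under 0.1%, and the spatial pass (SpCC) removes the
remaining isolated errors. The K-means baseline, working on one
composite gray-level image, is far behind at this noise level.

Single-voxel estimator statistics:

```r
wm <- brain_phantom_tissues()[[1]]
mc <- monte_carlo_voxel_study(wm, n_reps = 5000, seed = 1)
cor(mc$estimates$rho, mc$estimates$t2)
#> [1] -0.8947598
```

The command-line front end (`inst/cli/relaxseg.R`) exposes the same
pipeline as `simulate`, `estimate`, `segment`, `evaluate` and
`reproduce-phantom-study` subcommands.

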