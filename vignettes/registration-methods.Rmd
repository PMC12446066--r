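---
title: "Automated volume-CLEM registration: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated volume-CLEM registration: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Volume correlative light and electron microscopy (vCLEM) images one sample
twice: a fluorescence z-stack (FM) that reports molecular identity, and a
volume-EM stack that reports ultrastructure. The two volumes differ in voxel
size, orientation, field of view and contrast mechanism, so establishing
which EM structure carries which fluorescent label requires a 3D cross-modal
registration. Manual registration — clicking corresponding landmarks in both
volumes — takes hours of expert time and is the accepted baseline.

`clemalign` automates this registration through a landmark-organelle route:
mitochondria are segmentable in both modalities, are numerous, and are
distributed throughout the cell, which makes them good *off-target*
landmarks (the registration never sees the biological target channel, which
avoids circularity when the overlay is later used to interpret that
channel). The pipeline is

1. segment mitochondria in the FM channel (thresholded
   Laplacian-of-Gaussian);
2. take an externally produced EM mitochondria instance segmentation as
   input (in practice from a pretrained deep model; this package never
   computes it);
3. resample both masks to a common isotropic grid and sample point clouds
   from the mask surfaces;
4. reduce the clouds and register them with coherent point drift (CPD);
5. warp the FM channels onto the EM grid with the fitted transform.

## FM landmark segmentation

The FM channel is min–max normalized to $[0,1]$,
$x_{\mathrm{scaled}} = (x - x_{\min})/(x_{\max} - x_{\min})$, and filtered
with a difference of Gaussians (DoG) applied as separable 1D convolutions
along z, y and x. The two scales obey $\sigma_2/\sigma_1 = 1.6$, the
classical ratio at which a DoG approximates the Laplacian of Gaussian;
`dog_sigmas(3.0)` gives $(3.0, 4.8)$ px. Defaults $\sigma = 3.0$,
$T = 1.2$ suit pairings with near-isotropic EM; $\sigma = 2.2$, $T = 1.3$
suit strongly anisotropic (serial-block-face-like) pairings.

The response is thresholded per z-slice at $T$ times a slice statistic.
The statistic is the one genuinely open design point, because a signed DoG
response has a near-zero slice mean that makes $T \approx 1.2$
meaningless. `dynamic_threshold()` offers three statistics:

* `reference_mean` (default): the mean intensity of the corresponding slice
  of the normalized *input* volume. It scales directly with the slice's
  signal content, so noise-only slices produce empty masks, the threshold
  tracks depth-dependent signal attenuation (its stated purpose), and
  $T = 1.2$–$1.3$ lands near the half-height of the blob response so
  segmented boundaries track object boundaries;
* `positive_mean`: the mean of the positive part of the response. On
  noisy stacks this statistic is dominated by filtered noise, so slices
  without signal keep large speckle sets — it is retained for
  low-noise/deconvolved data;
* `mean`: the raw slice mean, for completeness.

Connected components (26-connectivity, compiled labeling) below the 5th or
above the 95th percentile of the component-size distribution are then
removed — inclusive at the boundaries, linear-interpolation percentiles.
This percentile filter is designed for speckle-rich stacks where most
components are spurious. In `run_pipeline()` the *upper* cut is disabled by
default (`size_pct_high = 100`): once the dynamic threshold has already
suppressed speckle, every large component is a real landmark (or a merged
cluster of them) and trimming the top 5% of components can only delete true
registration signal. `segment_fm()` itself keeps the classical 5/95
defaults. Yen-threshold clipping of overexposed puncta (`clip_overexposed`)
is available as an optional preprocessing step.

## Point clouds

Both masks are resampled to an isotropic grid (default 20 nm; output shape
is `round(extent_nm / target_nm)` per axis, nearest-neighbor for labels) and
a 2D Canny filter ($\sigma = 1$ px) is applied to every binarized z-slice;
each edge pixel becomes a `(z, y, x)` point, ordered z-then-row-major so
runs are reproducible without a seed. The cloud is reduced by three stages:
uniform downsampling (every $k$-th point, $k = 30$), voxel binning on a
$15^3$-pixel grid anchored at the coordinate origin (one mean point per
occupied cell; anchoring at the origin keeps the FM and EM grids
commensurate), and statistical outlier removal (drop points whose mean
distance to their 20 nearest neighbors exceeds the cloud mean by 2 sd;
both parameters are conventional defaults, exposed in the configuration).

## Registration: coherent point drift

`cpd()` implements the EM iterations of coherent point drift from first
principles. The transformed source points are the centroids of an isotropic
Gaussian mixture with shared variance $\sigma^2$ and optional uniform
outlier component of weight $w$; the target points are the data. The E-step
computes soft correspondences $P$; the M-step solves the transform in
closed form — for the rigid family, rotation from the SVD of the weighted
cross-covariance (re-projected to $\det R = +1$ every iteration), then
scale, translation, and the $\sigma^2$ update; the affine family replaces
the SVD with a linear solve; the nonrigid family is the Gaussian-kernel
coherent variant, solving
$(\mathrm{d}(P\mathbf 1)G + \lambda\sigma^2 I)W = PX - \mathrm{d}(P\mathbf 1)Y$
with kernel bandwidth $\beta$ and stiffness $\lambda$ (as
$\lambda \to \infty$ the displacement field vanishes). The nonrigid slot
deliberately implements this classical variant rather than the full
Bayesian machinery: rigid alignment is the primary path (it outperformed
nonlinear warping on the real benchmarks), and the classical formulation is
fully specified by the closed-form updates above.

Numerical choices: clouds are centered internally and the translation
recomposed on output; $\sigma^2$ is initialized at the mean squared
cross-distance and floored at $10^{-12}$; iterations stop at
$|\Delta\sigma^2| < 10^{-6}$ or after `max_iter = 50` iterations. The
negative log-likelihood is recorded every iteration (`nll_trace`) and is
non-increasing, which the test suite asserts; $\sigma^2$ itself need not be
monotone. The default $w = 0$ matches the reference implementation the
original pipeline called; note that $w > 0$ combined with scale estimation
can collapse the scale on clouds whose surfaces disagree systematically
(mass is dumped on the uniform component), which is why the outlier term is
off by default. With both clouds on a common nm grid the fitted scale
should be ~1 — the acceptance suite asserts $|s - 1| < 0.05$.

The fitted transform is returned in pixel units of the isotropic grid;
`to_physical()` scales the translation by the grid step (the rotation is
unit-free), and `to_pixel()` inverts the conversion exactly.

## Warping

`affine_warp_volume()` uses inverse projection: each output voxel $p$
samples the input at $T^{-1}(p)$, with spline interpolation of order 0, 1
or 3 (order 3 is a Keys cubic-convolution kernel, i.e. an interpolating
cubic; order 1 exact trilinear). Samples outside the grid contribute 0.

`tps_warp_volume()` applies a 3D thin-plate spline fitted by `tps_fit()`
with the 3D biharmonic kernel $\varphi(r) = r$ (the fundamental solution in
three dimensions, not the 2D $r^2\log r$) and zero regularization, so
control pairs are interpolated exactly and the kernel weights satisfy the
side conditions $\sum_i W_i = 0$, $\sum_i W_i C_i^\top = 0$; when the
control pairs follow an affine map the kernel weights vanish. The field is
fitted in the *output* space (registered FM control points mapped back to
their original FM positions), matching the inverse-projection convention.
The output grid is processed as $2 \times 2 \times 2 = 8$ sequential chunks
to bound memory; evaluation is pointwise, so the chunked result is
bit-identical to the monolithic one (asserted). An approximate-grid
accelerator (`grid_step`) evaluates the spline on a coarse grid and
interpolates the mapped coordinates; the exact per-voxel path is the
reference and the default.

`resample_to_em()` finally resamples the warped volume onto the EM grid
geometry exactly (both grids share the coordinate origin, voxel centers at
integer coordinates).

## Evaluation metrics

* `overlap_volume`: intersected foreground voxels × voxel volume, in µm³.
* `mesh_centroid`: the level-0.5 isosurface vertex set (one linearly
  interpolated point per grid edge crossing the level — the marching-cubes
  vertex set; the triangulation itself is not needed for any metric), and
  the centroid is the unweighted vertex mean, in nm.
* `characteristic_length`: $L = V^{1/3}$, the size scale against which
  centroid errors are judged.
* `landmark_errors`: per-pair Euclidean distances of transformed moving
  landmarks to fixed landmarks.
* `landmark_noise_experiment`: both landmark sets are perturbed with seeded
  Gaussian offsets ($\mu = 0$, $\sigma = n$ px per axis, $n \le 10$) and an
  automated and a manual transform are compared by a two-sided two-sample
  Student's t-test with pooled variance (not Welch). The noise level at
  which the two become indistinguishable bounds the effective precision of
  manual annotation.
* `ablate_instances` implements the robustness protocols: `random` removes
  `round(fraction × n)` instances uniformly (seeded); `peripheral` /
  `central` rank instances by the distance of their centroid from the
  overall foreground centroid and remove the farthest / nearest first —
  a geometric operationalization of losing segmentations in different
  regions of the volume.
* `proximity_correlation`: Spearman rank correlation between each target's
  distance to the nearest landmark voxel and its registration error; tied
  ranks use average ranks.
* `evaluate_targets` mirrors the benchmarking recipe: each manually
  segmented EM target is cropped with its bounding box plus a 5-voxel
  margin, the warped FM channel is Otsu-thresholded inside that box, and
  the intersected volume, mesh-centroid distance and characteristic
  lengths are reported.

## The synthetic study conditions

`generate_fixture()` builds a paired FM/EM dataset with known ground truth,
sized for a desk-scale study. The defaults are the standard conditions used
throughout the tests and the acceptance analysis:

* EM grid $(80, 304, 304)$ voxels at 25 nm — a flat, adherent-cell-like
  field of $2 \times 7.6 \times 7.6$ µm. The cell is an ellipsoid with
  semi-axes 0.45 of the grid; the flat geometry limits axial stacking of
  landmarks, as in adherent cultured cells.
* 40 ellipsoidal mitochondria with full axes 800–1200 nm (major) by
  400–550 nm (minor) — textbook tubule dimensions — randomly oriented,
  non-overlapping, separated by ≥ 100 nm. Targets (five spheres of
  0.3–1 µm, the documented size range of the lysosome-class structures
  used for evaluation) are placed first because the largest spheres need
  the largest pockets; landmarks are placed largest-first for the same
  packing reason.
* Ground truth: a rigid rotation of 10° about z (about the volume center)
  plus a 15 px translation — the scale of residual misalignment left after
  the routine coarse prealignment such datasets receive.
* The FM stack lives on its own $(80, 40, 40)$ nm anisotropic grid
  (typical Airyscan sampling) with a margin around the EM extent, and is
  rendered by pulling the EM masks through the inverse ground-truth
  transform, blurring with a Gaussian PSF of $\sigma = (149, 51, 51)$ nm —
  the instrument's stated 350 nm axial / 120 nm lateral resolution read as
  FWHM — multiplying by an exponential depth decay (0.5%/slice) and adding
  Gaussian noise (sd 0.02 of the unit signal; optional Poisson resampling).

What the generator deliberately does *not* emulate: realistic EM texture,
detector-specific noise, deconvolution artifacts, mitochondrial networks
(instances are convex and disjoint), and membrane-bound organelle
substructure. Passing tests on this fixture therefore demonstrate the
geometry and statistics of the method — segmentation under blur,
attenuation and noise; cloud sampling; probabilistic registration; warping
— not performance on real stacks, where the EM segmentation model and the
imaging physics dominate.

Problem sizes were chosen so a full pipeline run takes on the order of a
minute and the five-seed ablation protocol minutes, which makes the whole
analysis reproducible interactively.

## Known limitations

* The FM segmentation boundary inherits the PSF: the warped-mask Dice
  against EM truth plateaus around 0.7 on the standard conditions, while
  the warped-intensity overlay segmented with Otsu reaches ~0.84; both are
  honest reflections of diffraction-limited boundary localization.
* CPD with $w = 0$ degrades when many *target* (EM) points have no source
  counterpart; the ablation experiment removes EM instances, which is the
  benign direction, matching the robustness the original study reports.
* The nonrigid path is the classical coherent-drift variant; it is a
  secondary route and rigid warping remains the default overlay path.
* 2D slice-wise Canny is applied in the z orientation only, following the
  per-slice description of the surface-sampling step.
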