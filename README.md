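# clemalign

Automated 3D registration of fluorescence microscopy (FM) z-stacks onto
volume electron microscopy (EM) stacks — the registration step of volume
correlative light and electron microscopy (vCLEM).

## The problem and the approach

A vCLEM experiment images one sample twice: an FM stack that says *what* a
structure is (molecular labels) and a volume-EM stack that says *what it
looks like* (ultrastructure). Interpreting the EM requires warping the FM
channels onto the EM grid. Done manually — clicking paired landmarks in
both volumes — this takes an expert hours. `clemalign` automates it using
mitochondria as off-target landmarks:

1. **FM segmentation** — thresholded Laplacian-of-Gaussian: min–max
   normalization, separable difference-of-Gaussians with scale ratio
   σ₂/σ₁ = 1.6 (default σ = 3.0 px), a per-slice dynamic threshold
   (default T = 1.2) that tracks depth-dependent signal attenuation, and a
   connected-component size filter.
2. **EM segmentation** is an *input* (a label TIFF, in practice from a
   pretrained deep model) — never computed here.
3. **Point clouds** — both masks are resampled to an isotropic grid
   (20 nm), a per-slice Canny filter (σ = 1) turns mask surfaces into
   points, and the clouds are reduced by uniform downsampling (every 30th
   point), 15³ voxel-grid binning and statistical outlier removal.
4. **Registration** — coherent point drift (CPD), implemented from the
   Gaussian-mixture EM formulation with closed-form M-steps: rigid
   (SVD rotation + scale + translation; the default, 50 iterations),
   affine, or a Gaussian-kernel nonrigid variant. `cpd()` is a standard
   S3 model function with `print`, `summary`, `coef`, `predict`, `plot`
   and `logLik` methods.
5. **Warping** — inverse-projection affine warping with spline
   interpolation, or 3D thin-plate-spline warping (kernel φ(r) = r,
   eight-chunk execution), then exact resampling onto the EM grid.

Evaluation utilities implement the registration-quality metrics —
intersected volumes (µm³), marching-cubes mesh centroids and their
Euclidean distances, characteristic lengths L = V^(1/3), landmark error
distributions with a Student's t-test noise experiment, instance-ablation
robustness protocols and Spearman proximity–accuracy correlation — plus a
fully synthetic paired-volume generator with known ground truth so the
entire pipeline is testable offline.

## Worked example

Generate the standard synthetic study conditions (40 mitochondria-like
landmark ellipsoids in a flat cell, EM grid 80×304×304 at 25 nm, FM stack
on its own 80×40×40 nm grid with PSF blur, attenuation and noise, and a
known rigid ground truth of 10° rotation plus a 15 px translation), then
run the full pipeline:

```r
library(clemalign)

fx  <- generate_fixture(fixture_spec(seed = 1))
cfg <- pipeline_config(fm = fx$fm_landmark, em_labels = fx$em_labels,
                       channels = list(landmark = fx$fm_landmark),
                       landmarks = fx$landmark_pairs)
res <- run_pipeline(cfg)
print(res)
#> CLEM registration pipeline result
#> Coherent point drift (rigid): 774 -> 643 points, 50 iteration(s)
#>   residual variance sigma^2 = 37.3522
#>   scale = 0.992245, |t| = 62.64, rotation angle = 10.51 deg
#>   FM cloud 774 pts, EM cloud 643 pts
#>   mean landmark error = 30.5 nm (n = 40)

seg <- otsu_segment(res$overlays$landmark)
dice_coefficient(seg, res$em_mask_iso)
#> [1] 0.8384179
```

Reading the numbers: the fitted rigid transform recovers the 10° ground
truth to half a degree (10.51°), the fitted scale is ≈1 as it must be when
both clouds share a common nm grid, the mean error over the 40 held-out
landmark pairs is 30.5 nm — about one EM voxel — and the warped,
Otsu-segmented landmark channel overlaps the EM mitochondria mask with a
Dice coefficient of 0.84.

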