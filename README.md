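# hogreg

Rigid registration of 2D multi-modal brain MRI slices, driven by the
mutual information of histogram-of-oriented-gradients (HOG) feature
distributions.

## The problem

Diffusion-weighted MRI is acquired slice by slice and is very sensitive to
head motion — the stronger the diffusion weighting (*b*-value), the worse.
Before a diffusion stack can be compared with a structural T2-weighted
reference of the same subject, each slice pair must be brought into the
same coordinate system. The two modalities show the same anatomy with very
different intensities (ventricles, cortex and white matter can even swap
contrast), so similarity measures based on raw intensity agreement are
unreliable: classical intensity-based mutual information develops spurious
local maxima that trap the optimization.

`hogreg` implements a coarse-to-fine rigid registration that sidesteps
this: sparse geometric features (Harris corners) estimate the translation,
and the rotation is found by maximizing mutual information computed not
from intensities but from HOG descriptors, which encode local gradient
*orientation* structure — stable across modalities even when intensity
mappings are not. It is aimed at researchers working with small 2D
slice-pair datasets who want a transparent, exhaustively searched,
fully inspectable registration rather than a black-box optimizer.

## The method

A rigid transform with rotation angle θ (degrees) and translation
τ = (τx, τy) (pixels) maps a pixel **x** as

    T(x) = Θ (x − c) + c + τ,        Θ = [cos θ  −sin θ; sin θ  cos θ]

with pivot **c** at the image center. The registration solves

    T* = argmax over (θ, τ) of  Metric[ I_fixed, I_moving ∘ T⁻¹ ]

by exhaustive search on a grid (defaults: τ from −5 to +5 px in 0.5 px
steps per axis, θ from −5° to +5° in 0.5° steps):

1. **Coarse translation.** Harris corners (response `det M − k·tr²M` of
   the windowed second-moment matrix M, `k = 0.05`) are detected in both
   images and matched by mutual nearest neighbors; the mean Euclidean
   distance (ED) between matched corners, evaluated over the translation
   grid, is minimized.
2. **Fine rotation.** With τ frozen, each candidate θ is scored by the
   mutual information `MI = H(p) + H(q) − H(p,q)` (base-2 logs) between
   the quantized HOG feature vectors of the fixed image and of the
   rotation-corrected moving image. HOG uses 8×8-px cells, 16×16-px
   blocks of 2×2 cells with one-cell stride, 9 unsigned orientation bins
   and per-block L2 normalization — 34,596 features for a 256×256 slice.
   The two stages alternate until the estimates reproduce themselves.
3. **Accuracy.** The fiducial registration error (FRE) over up to 30
   matched corner fiducials is reported as RMS, mean and SD, in pixels
   and millimetres.

An intensity-based MI mode (`similarity = "mi_intensity"`) provides the
classical baseline for comparison.

Because suitable public T2w/DTI slice pairs are scarce, the package ships
a synthetic multi-modal brain phantom generator with known ground-truth
transforms (`generate_phantom_pair()`), used throughout the test suite.

## Worked example

```r
library(hogreg)

# a multi-modal phantom pair misaligned by theta = -2 deg, tau = (-4.5, -4.5) px
ph  <- generate_phantom_pair(size = 256, seed = 7,
                             true_transform = rigid_transform(-2, -4.5, -4.5))
fit <- register(ph$fixed, ph$moving)
fit
#> <hog_registration> method mi_hog
#>   theta = -2 deg, tau = (-4, -4.5) px
#>   FRE rms 1.15 px, mean 0.89 px (|Omega| = 30)

glance(fit)
#> # A tibble: 1 x 13
#>   method theta tau_x tau_y mi_max ed_min fre_rms fre_mean fre_sd omega ...
#> 1 mi_hog    -2    -4  -4.5  0.489   1.74    1.15    0.890  0.748    30 ...
```

The true rotation is recovered exactly and each translation component to
within one 0.5 px grid step; the residual FRE of ~1 px reflects the
corner-localization noise between the two synthetic modalities. `tidy(fit)`
returns the MI-vs-θ trace, `autoplot(fit)` plots it with the recovered
angle marked, and `plot_ed_surface(fit)` shows the coarse-stage ED
surface. `write_registration(fit, dir)` exports the result JSON, trace and
fiducial CSVs, and the resampled moving image.

A thin command-line wrapper is installed with the package
(`exec/hogreg`):

```sh
hogreg phantom  --size 256 --seed 7 --theta -2 --tau -4.5 -4.5 --out ph/
hogreg register --fixed ph/fixed.nii.gz --moving ph/moving.nii.gz --out reg/
```

## Scope

2D rigid (rotation + translation) registration only: no affine or
deformable models, no 3D volumetric registration, no multi-resolution
optimizers — slices from 3D volumes are handled independently per slice.
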