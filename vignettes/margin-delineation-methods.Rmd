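---
title: "Methods: image-guided Raman probe tracking and margin delineation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-guided Raman probe tracking and margin delineation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanmargin)
```

# The system

Intraoperative tumor margin delineation asks a simple question at many
points: *is the tissue under the probe tip diseased?* A fiber-optic Raman
probe answers it spectroscopically, one point at a time; the missing piece
is knowing *where* each answer was taken. `ramanmargin` implements the full
chain of a video-guided solution:

1. two colored fiducial markers on the probe shaft are segmented in each
   video frame (HSV color space),
2. the known physical marker geometry converts the pixel pair into an image
   scale and an extrapolated tip position,
3. each spectral acquisition is classified (PLS-DA after a fixed
   preprocessing chain) and pinned to the tracked tip,
4. positive points are connected into a lesion boundary, expanded by a
   clinician-chosen safety margin, and
5. the delineation is scored against ground truth as true-positive /
   false-negative / false-positive areas.

Because tissue and phantoms are not available at a desk, every input is
produced by first-class synthetic generators with exact ground truth. This
vignette records the models, the tunable parameters, and the design
decisions that were genuinely open.

# Probe tracking

## Model and assumptions

Markers are detected per frame by thresholding in HSV space: hue within a
tolerance of the calibrated center (measured on the 360° circle, so red
markers straddling 0° behave correctly), saturation and value above
minima. HSV is preferred to RGB because it decouples chromaticity from
luminance: a brightness change that keeps V above `val_min` does not move
the segmentation. The binary mask is cleaned with a 3×3 morphological
opening then closing, and the largest connected component supplies an
unweighted pixel centroid — appropriate because markers are rendered (and
in practice manufactured) as uniform saturated disks. Components smaller
than `min_area_px` (default 20 px) are reported as misses, which are data,
not errors.

With centroids $p$ (proximal) and $d$ (distal) and the probe's physical
marker separation $s$ (mm) and tip offset $o$ (mm), the per-frame scale and
tip are

$$\text{mm/px} = \frac{s}{\lVert d - p \rVert}, \qquad
  \hat{t} = d + (d - p)\,\frac{o}{s}.$$

The estimate is equivariant under translation, rotation and uniform
scaling of the marker pair; scaling rescales mm/px inversely. Computing the
scale *per frame* rather than once at calibration means that changes in
working distance degrade accuracy gracefully instead of silently — tracking
accuracy and the physical size of a safety margin both depend on working
distance, and the per-frame scale makes that dependence visible in the pose
table.

Two colinear markers are the minimal geometry for this ratiometric
extrapolation and are what the package supports; marker identity (which is
distal) is fixed by color, not by position, so any in-plane orientation is
unambiguous. The tracker holds **no temporal state**: row $i$ of the pose
table depends only on frame $i$ and the calibration, so the system recovers
immediately after the probe leaves and re-enters the field of view.

## Calibration

`calibrate_hsv()` needs one manually identified pixel per marker. A 7×7
neighborhood around the seed supplies a circular-mean hue and
5th-percentile saturation/value minus a slack of 0.1. A seed on a
low-saturation region (median S < 0.2) is rejected, as are two seeds whose
hue windows overlap — markers that cannot be told apart are a configuration
error, not a tracking miss.

## What the synthetic video does and does not emulate

The generator renders anti-aliased saturated disks (green 120°, blue 240°
by default) on a low-saturation gray scene, places them by inverting the
tip formula from a known trajectory, and can hide them entirely on
designated occlusion frames. The default conditions mirror the bench
protocol: 180 frames at 640×480 and 0.5 mm/px, 20 mm marker separation,
30 mm tip offset, 8 px marker radius. Ground truth is exact by
construction, so no manual annotation (or its averaging) is involved.

Deliberately *not* modelled: photorealistic tissue texture, lens
distortion, motion blur, specular highlights, and partial (as opposed to
complete) marker occlusion. Passing the tracking tests therefore
demonstrates the correctness of the segmentation/extrapolation chain and
its sub-pixel behavior on clean scenes — the reported ~0.14 mm mean error
on synthetic video is a floor, not a prediction for surgical video, where
the bench system itself reports on the order of 1 mm.

# Spectral preprocessing

Every spectrum passes the same fixed chain, in this order:

| step | operation | parameters (defaults) |
|---|---|---|
| 1 | crop to fingerprint region | 600–1800 cm⁻¹ |
| 2 | Whittaker background subtraction | λ = 100 000, p = 0.01, 10 iterations, 2nd-order differences |
| 3 | normalization | area under the curve = 1 (`max`, `vector` available) |
| 4 | Savitzky–Golay filter | order 1, frame 7, mirror padding |

The Whittaker filter is used here for *background estimation*, not
smoothing, so it is implemented as asymmetric penalized least squares: the
baseline $z$ minimizes
$\sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^2 z)_i^2$
with weights re-estimated each round ($w_i = p$ where $y_i > z_i$, else
$1-p$), which pushes $z$ to the lower envelope — the fluorescence
background — while λ = 100 000 keeps it too stiff to follow Raman bands.
The asymmetry $p = 0.01$ and 10 iterations are package defaults chosen from
common practice with this estimator; they are recorded in
`preprocess_config()` and covered by tests, and can be changed per run.
The linear system is banded and solved sparsely (O(n) per iteration); a
dense solve of the same normal equations serves as the independent test
oracle.

Area normalization is the default in every workflow, with the mode switch
retained for sensitivity analysis. Savitzky–Golay edge handling is mirror
padding, which preserves length and avoids transients at the 600/1800 cm⁻¹
boundaries; for order 1 and frame 7 the interior coefficients coincide with
a 7-point moving average, a property the tests exploit as an oracle.

Two invariances summarize the chain's correctness: it commutes with
positive scaling of the raw counts (laser power/integration time cancel),
and the background estimator is shift-equivariant (adding a constant moves
the baseline by the same constant).

# Classification

PLS-DA is PLS2 regression of one-hot class indicators on mean-centered
spectra, fit by NIPALS: successive orthogonal latent variables maximizing
X–Y covariance. Features are centered but **not** variance-scaled by
default — the spectra are already area-normalized, and autoscaling would
inflate noise-only wavenumbers; a `scale` flag exposes the alternative.
The number of latent variables defaults to 2 (the pair conventionally
inspected as LV1/LV2 score plots) and is overridable.

Prediction takes the argmax of the per-class continuous responses. For
margin work one class is designated *positive* and an adjustable threshold
(default 0.5) applies to its response only; lowering the threshold can only
add positives, a monotonicity the tests assert. Whether a Bayesian
per-class threshold would match the original modelling tool is unknowable
from the outside; the fixed 0.5 default is documented and adjustable.

Venetian-blinds cross-validation assigns sample $i$ (1-based, dataset
order) to fold $((i-1) \bmod k) + 1$ — a pure function of the index,
reproducible without seeds. The default $k = 10$ is reduced automatically
to the smallest class size when classes are small. Perfectly separable
synthetic classes (disjoint peak sets, noise SD 0.3 against peak heights
~10) yield 100% cross-validated accuracy; label permutation collapses it to
chance, and both behaviors are pinned by tests.

PCA (`pca_scores()`) supports the phantom-discrimination analysis: the
strongly fluorescent (20-unit) analog is separated on PC1 when PCA is run
on *cropped, unsubtracted* spectra — deliberately so, because the
discriminating signal there **is** the broad fluorescence background that
the Whittaker step would otherwise remove.

# Margin delineation

Positive diagnosis locations are "connected to form a boundary" as their
convex hull — the simplest boundary consistent with a single compact
lesion. The delineated region is the hull expanded outward by an effective
radius

$$r = \text{margin}_\text{mm} + \tfrac{1}{2}\,\text{tip diameter}_\text{mm},$$

converted to pixels with the **median** per-acquisition mm/px across the
store (robust to single-frame scale noise). The half-tip term reflects
that a 2.1-mm probe tip senses a disk, not a point; it can be switched off
for pure-geometry analyses. Degenerate cases are defined, not special-cased
away: 0 positives → empty mask, 1 → disk, 2 → capsule. Masks use half-open
pixel coverage (a pixel belongs to the region iff its center does) and are
clipped to the frame. The buffered outline is produced by support-function
sampling of the convex set at 0.5° resolution, which is exact for convex
regions up to that angular discretization.

Monotonicity properties follow directly and are tested: growing the margin
nests the masks, adding a positive never shrinks the region, and the result
depends on the *set* of positives, not their acquisition order — which,
combined with the append-only diagnosis store, is what makes delineation
robust to temporary probe occlusion.

Known limitation: spatially disjoint positive clusters are wrapped in one
hull. A concave (alpha-shape) or multi-component boundary is a deliberate
non-goal of this implementation.

`suggest_points()` proposes the next acquisitions on the boundary offset
outward by the requested spacing, at arc-length intervals of that spacing,
excluding sites within one spacing of any existing measurement — around a
single positive this degenerates to a ring, which the tests check
geometrically.

# Fluorescence comparison arm

The wide-field fluorescence image of a scene is modelled as
$I = g\,C\,e^{-\mu d} + \varepsilon$: gain × concentration attenuated
exponentially by the occluding-layer thickness $d$, plus Gaussian noise.
`fluorescence_delineation()` thresholds it at a fixed value or an automatic
bimodal (Otsu) threshold; a flat image has no bimodal split and is an
error. This is intentionally the *simplest defensible* fluorescence
pipeline: the comparison of interest is structural — thresholded
fluorescence cannot see a non-fluorescent (0-unit) or occluded
low-concentration region, while Raman classification is indifferent to
fluorescence because the background is removed in preprocessing. The
acceptance properties assert exactly that directional contrast rather than
any specimen-bound percentage.

# Evaluation conventions

TP, FN and FP pixel areas are expressed as percentages of the
ground-truth area, so TP + FN = 100 exactly and FP is unbounded above; this
denominator is the one consistent with delineation summaries of the form
86.5/13.5/21.7. The alternative (FP over delineated area) is available via
`fp_denominator = "pred"`. Tracking error is the per-frame Euclidean tip
distance converted to mm with the ground-truth scale, over valid frames
only, with invalid frames counted separately.

# Problem sizes and numerical choices

The test battery runs the study conditions at full scale where the claim
demands it (the 180-frame 640×480 tracking run; 25 + 25 spectra through the
complete chain with 10-fold venetian-blinds CV) and at reduced scale where
only a property is at stake (unit tests use ~8–24-frame 320×240 videos and
6–10 spectra per class). Axis resolution is 2 cm⁻¹ over 400–2000 cm⁻¹,
giving 601 points in the fingerprint window. Tolerances follow the source
of error: exact identities at 1e-9–1e-12, banded-vs-dense solver agreement
at 1e-6, rasterized areas at 5%. Ties in argmax classification resolve to
the first class in sorted order; hue distances are compared inclusively at
the tolerance; the Whittaker solver's weights start at 1 (symmetric) so the
first iteration is a plain smoother from which the asymmetric envelope is
refined.

# Reproducibility

Every generator is a pure function of its spec and an integer seed; the
workflow fans one master seed out to named substreams (spectra, per-frame
acquisition noise). `run_experiment()` and `cmd_simulate()` therefore
regenerate byte-identical artifacts from a config + seed, which the tests
verify at the file level.
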