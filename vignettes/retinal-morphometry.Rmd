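---
title: "Methods: automated retinal vascular morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated retinal vascular morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retmorph)
```

`retmorph` measures the morphology of the retinal vasculature on
optic-disc-centred fundus photographs: vessel diameter, tortuosity,
fractal dimension, density, branching angle, arteriole-to-venule ratio,
and their zonal breakdown around the optic disc. This vignette explains
the underlying procedures, the parameters that matter, the numerical
choices made where the mathematics alone does not dictate one, and what
the synthetic-phantom validation does and does not establish.

## Image model and preprocessing

Inputs are 8-bit RGB fundus photographs held as `H x W (x 3)` matrices
with intensities in `[0, 255]`; coordinates are 1-based pixel centers
with `x` the column and `y` the row. The conditioning chain runs in the
order *ROI extraction → median denoising → mean calibration and
resampling → CLAHE enhancement*:

* **ROI**: the camera aperture is recovered by thresholding the red
  channel at 1/3 of its mean grey value, keeping the largest connected
  component, and smoothing its boundary by morphological opening (disk
  of radius 5 px at a 1024-px working size, scaled proportionally). The
  comparison is `>=` with a strict-positive guard, so an all-zero image
  raises an error rather than returning a spurious full-frame ROI.
* **Denoising**: an odd-sized median filter (default 3), with explicit
  reflection padding so border pixels see a full window.
* **Calibration**: each channel's mean is moved to a reference mean.
  Both an additive shift (default) and a multiplicative gain are
  provided; the additive form was chosen as the default because it
  preserves local contrast exactly, which the later measurement stages
  depend on, while the gain form distorts dark vessel profiles more.
  Resampling to a uniform size uses corner-aligned bilinear
  interpolation. Inside `analyze()` the image is *not* resampled, so
  user-supplied masks stay pixel-aligned with the image.
* **Enhancement**: contrast-limited adaptive histogram equalization
  (clip 2.0, 8 × 8 tiles) applied to the grayscale conversion. The
  grayscale weights default to `(0.299, 0.587, 0.144)`; note the blue
  weight, whose sum with the others is 1.030, so neutral grey 100 maps
  to 103. The conventional BT.601 triple (blue 0.114) is available via
  `gray_coeffs("bt601")` for users who prefer exact mean preservation.

Whether enhancement should run per channel or on the grayscale image is
an open choice; it runs on the grayscale here, since every downstream
consumer of the enhanced image (Otsu, the polar disc trace) is
single-channel.

## Vessel candidates and segmentation evaluation

When no vessel mask is supplied, classical stages produce one: Otsu's
threshold (between-class variance maximization over ROI pixels only)
extracts the dark region, and connected components are filtered by
morphology — elongation ≥ 3 (major/minor axis ratio of the component's
second-moment ellipse), maximum inscribed width ≤ 40 px, area ≥ 50 px
at a 1024-px working size. These defaults keep thin elongated
structures and reject blobs and specks; they are deliberately
conservative, and a curated segmentation (e.g. from a trained model or
manual annotation) supplied as a mask is always preferred for real
studies. Component analysis uses 8-connected labeling, since vessels
routinely touch diagonally.

Segmentation quality is scored pixelwise with accuracy, sensitivity,
specificity, IoU, and DICE (`2TP/(FP+2TP+FN)`), restricted to the ROI
by default (a full-frame flag exists). Ratios with zero denominators
are reported as missing rather than zero, distinguishing "no positives
exist" from "all positives missed". With several images, scores can be
pooled over one accumulated confusion matrix (default) or averaged per
image; the two differ whenever image difficulty varies, which is why
both are exposed.

## Optic disc segmentation and calibration

The disc is the calibration object: its diameter (PD) is taken as
1.5 mm, giving `mm_per_px = 1.5 / PD_px`. The pipeline:

1. **Seed**: the centroid of the largest bright component after
   Gaussian smoothing (σ = 5 px), thresholded midway between the median
   intensity and the 99th percentile. The midway cut is deliberate — a
   cut exactly at the percentile is unstable on flat-topped bright
   regions. A user seed bypasses the heuristic.
2. **Boundary**: the image is sampled on a polar grid about the seed
   (360 angles, radial step 0.5 px, `r_max` = 0.4 × frame side) and a
   1-D derivative-of-Gaussian operator (σ = 2 px) is applied along each
   radial column; the boundary radius per angle is the strongest
   bright-to-dark response, median-smoothed across angles (window 9) to
   suppress angles corrupted by vessels crossing the disc rim.
3. **Circle**: the minimum enclosing circle of the boundary points
   (Welzl-style incremental construction with a deterministic scrambled
   insertion order) gives the final center and PD. Its correctness is
   tested against an exhaustive pair/triple oracle.

The enclosing circle makes the PD robust to angles where the trace
undershoots (e.g. along a vessel), since only outermost boundary points
support the circle.

## Centerline graph

The vessel mask is thinned to a 1-px, 8-connected skeleton by
iterative two-subcycle parallel deletion of simple boundary pixels,
which preserves connected components and loops. Parallel thinning
leaves two well-known artefacts — staircase corner pixels and
two-pixel-thick diagonal joints — which masquerade as spurious branch
points; a sequential cleanup removes any pixel whose foreground
neighbours remain a single 8-connected component without it (endpoints
excluded), yielding a minimal skeleton with unchanged topology.

Nodes are classified by 8-neighbourhood degree: one neighbour is an
endpoint, three or more a branch point. Digital skeletons render one
anatomical bifurcation as a small cluster of high-degree pixels, so
branch pixels within 2 px are merged into one node; junctions of wide
vessels can still split into *two* nearby branch nodes joined by a stub
or a tiny loop, so branch-branch segments up to 10 px are additionally
contracted into a single node. Ordered pixel paths between nodes are
extracted deterministically (fixed scan order, 4-adjacent continuations
preferred over diagonal ones), terminal spurs shorter than 10 px are
pruned, and artery/vein labels attach to segments by majority vote over
an optional label mask. The 10-px pruning threshold sits below the
25-px curvature end-exclusion, so pruning never silently removes
geometry that tortuosity would otherwise measure.

## Morphometry

**Diameter.** At every 5th path pixel (and at least 7 px from a node),
the local tangent is the principal axis of the ±7 surrounding path
pixels; rays marched along the normal in both directions (step 0.25 px,
nearest-pixel membership, boundary refined to the midpoint of the last
inside and first outside sample) meet the vessel boundary at two
points whose Euclidean distance is the diameter. A ray leaving the
image before leaving the mask marks the section unmeasurable. The
micrometre value is `d_px × mm_per_px × 1000`.

**Tortuosity.** The curvature at path point A uses the two points B, C
at 25 px arc distance on either side: `C_A = 2 sin A / a` with `a = |BC|`
(the inverse circumradius of triangle ABC); `sin A < 1e-6` is treated
as collinear, curvature 0, which handles the formula's singular point
stably. The first and last 25 px of each segment are excluded. The
reported tortuosity is the mean over all samples (pooled, the default)
or the mean of per-segment means; both readings of "average curvature"
are defensible, and pooling was chosen as the default because it
weights vessels by measured length instead of equally. Units are
px⁻¹, scaled ×1000 for reporting; a config switch converts to mm⁻¹ via
the disc calibration, since the conventional unit is ambiguous.

**Fractal dimension.** Box counts are taken at dyadic scales ε = 4 …
`min(H, W)/4`; at each scale the count is the *minimum* over quarter-box
grid offsets in each axis (minimal covering). With a single anchored
grid the coarse scales hold only a handful of boxes and their partial
occupancy makes the fitted slope drift by several hundredths under
mere image translation; the minimal-covering count removes that
artefact while leaving the line (≈1), disk (≈1.9), and Sierpinski
carpet (≈1.89) references in range. The slope comes from ordinary
least squares on `(log(1/ε), log N)` and the full series is retained
for inspection.

**Density.** An exact pixel ratio `ρ = S′/S` of vessel over ROI area —
no estimation involved.

**Branching angle.** Within 2 PD of the disc border, the retina is
split into halves at the disc center's row, and the segment chain with
the largest mean diameter in each half is the main vessel (chains
extend through branch nodes into the widest eligible continuation;
ties go to the lower segment id). At each branch node on a main: the
main-vessel direction is fitted downstream (the incident main segment
whose far end lies farther from the disc center), the branch direction
along its arm, each as a least-squares line over the path pixels at
arc distance 10–20 px from the node. The first 10 px are excluded
because thinning distorts the centerline inside the junction plateau —
with an 11-px main vessel, fitting the first 10 px biases a designed
45° angle to ≈70°, while the 10–20 px window recovers it to within
0.5°. Arms too short for the window are skipped. The reported angle is
the mean over branch nodes within 2 PD.

**AVR** is the mean arteriolar over mean venular diameter of the
analyzed region; per-zone AVR uses per-zone means.

## Zonal analysis

A measurement point at distance `(‖p − center‖ − PD/2)/PD` (in PD units
from the disc *border*) belongs to the zone whose half-open interval
`[inner, outer)` contains it: C1 = [0.5, 1.0), C2 = [1.0, 1.5),
C3 = [1.5, 2.0), C4 = [2.0, 2.5). Half-open intervals resolve boundary
ties deterministically; a cross-section is assigned by its centerline
point, not its boundary points. Global metrics use all measurable
samples by default, including the sub-0.5-PD peripapillary region; a
flag excludes the disc neighbourhood for users who want the global
means consistent with the zonal ones.

## Phantoms: what the validation shows

`generate_phantom()` rasterizes bars, arcs, rings, Y-junctions,
X-crossings, Sierpinski carpets, bright discs, and composite fundus
scenes by exact pixel-center inclusion; ground-truth fields (width,
curvature, angle, density, fractal dimension, disc geometry) are
analytic functions of the specification, never measurements.
`phantom_fundus()` renders a bright disc (intensity 220) and dark
vessels (80) on a mid-grey background (140) inside a circular camera
aperture, with reddish channel weighting and seeded Gaussian noise
applied to the image only — masks stay exact, so measurement tests
isolate morphometry from segmentation error. Vessels run radially as
upper/lower artery/vein pairs (artery width 0.7 × vein width, matching
an AVR near the physiological ≈ 0.7) with optional side branches at a
designed angle. `generate_cohort()` grades vein width 8→16 px and
branch count 0→4 across the cohort so that measured diameter and
density must increase monotonically if the pipeline is faithful.

The suite and the acceptance script verify, on these phantoms:
curvature within 5% of `1/R` for radii 50–400 px; bar diameters within
1 px across widths 5–21 px and orientations 0–60°; the exact µm
conversion; exact densities; metric formulas to machine precision; the
enclosing circle against an exhaustive oracle; designed branch angles
within 3°; disc diameter within 2% for radii 30–150 px under seed
offsets up to 20%; zone assignment equal to the closed-form rule; and
byte-identical regeneration and re-analysis under a fixed seed.
Problem sizes were chosen so the whole suite runs in about two minutes:
phantom frames of 250–1024 px, a 10-member cohort at 560 px.

What phantoms do **not** show: robustness to real-world nuisance —
uneven illumination, central vessel reflex, crossings where arteries
and veins overlap, pathology (haemorrhages, drusen), blur, or
segmentation error. The classical Otsu stages are a baseline, not a
substitute for a trained segmentation model; on real images the
intended workflow supplies a vetted mask and lets `retmorph` do the
measurement. Phantom vessels are also straight or circular, so the
tortuosity validation exercises the estimator's accuracy, not the
biological range of tortuosity values.

## Degenerate inputs and tie-breaks

Constant images raise explicit errors in Otsu and the disc trace;
all-zero images fail ROI extraction. Empty masks skeletonize to empty
graphs and propagate missing metrics rather than errors inside
`analyze()`, which records stage failures in the bundle's `warnings`
and keeps partial results — for population runs a partially measured
image is more useful than a hard failure. Otsu ties return the midpoint
of the tied thresholds; main-vessel ties take the lower segment id;
X-crossings are kept as one degree-4 node with segments split there,
since A/V topology through a crossing is not inferable from a mask
alone.

## Known limitations

* Diameters are mask-geometric; no sub-pixel vessel-profile model
  (e.g. Gaussian fits) is applied, so they inherit the rasterization of
  the mask (±0.75 px on phantom bars).
* The brightness heuristic for the disc seed assumes the disc is the
  brightest large structure; severe peripapillary atrophy or overexposed
  lesions would mislead it — a user seed is the escape hatch.
* A/V labels are taken from the input label mask; the package does not
  classify vessels itself.
* Quadrant (superior/inferior/nasal/temporal) subdivision and
  CRAE/CRVE summary calibres are out of scope.
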