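---
title: "Methods: diel growth and nutation analysis in dielvision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diel growth and nutation analysis in dielvision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dielvision)
```

## The measurement problem

Circadian and diel growth studies need dense time-lapse sampling — minutes,
not hours — of organs that are simultaneously growing and nutating, under
an illumination regime that alternates between a bright photosynthetic day
period and a far-red night period that must not disturb the photoperiod.
Three things go wrong when such sequences are analysed naively:

1. **Organs escape the analysis window.** A fixed region of interest (ROI)
   drawn on the first frame is outgrown or nutated out of within a day.
2. **Measurements jump at every day/night switch.** Day and night frames
   come from different cameras, optics and gray statistics, so every
   pixel-counting variable (area, length, centroid, perimeter) shows a
   step at each transition that has nothing to do with the plant.
3. **Pixels are not millimetres**, and the mm-per-pixel scale depends on
   how far the organ sits from the camera.

`dielvision` addresses each: an adaptive ROI tracker, a per-transition
offset correction, and circle-grid metric calibration — plus a synthetic
chamber simulator that renders ground-truthed sequences so the whole chain
can be validated quantitatively.

## Segmentation chain

A frame is an 8-bit grayscale matrix (reference resolution 768 x 576, the
CCIR video format of the chamber cameras). The configurable chain
(`pipelineConfig()`) is: up to four preprocessing operations (average,
median, Laplacian, sharpen, custom 3x3/5x5/7x7 mask, or box-kernel
dilation/erosion/opening/closing, each with an iteration count), optional
polarity inversion, optional Roberts/Sobel edge magnitude, histogram
thresholding, 8-connected blob extraction, and blob filtering by min/max
area, compactness, length and perimeter. The default configuration —
median 3x3 then one opening, Otsu threshold — is a deliberately
conservative choice for a single bright organ on a darker background.
Edge detectors are offered as preprocessing for organs with kinky
outlines, but the segmentation mask always comes from thresholding, never
from the edge map itself.

### Thresholding

Three histogram criteria are implemented over the same candidate scan
(levels 0–254; foreground is strictly above the level; candidates that
leave a class empty are skipped; ties break toward the lowest level, which
makes every method deterministic):

* **Otsu** maximizes the between-class variance
  $\omega_0\omega_1(\mu_0-\mu_1)^2$.
* **Kapur** maximizes the summed Shannon entropies of the two classes.
* **Kittler–Illingworth** minimizes
  $J(t)=1+2[P_0\ln\sigma_0+P_1\ln\sigma_1]-2[P_0\ln P_0+P_1\ln P_1]$.
  Class variances are floored at $1/12$, the quantization-noise variance
  of integer gray levels; without the floor a class holding a single gray
  level has $\sigma=0$ and the criterion is undefined, and with it a
  cleanly bimodal two-level image is split identically by all three
  methods.

The test suite checks each method against an exhaustive brute-force scan
of all candidate levels on randomized histograms, and Otsu additionally
against EBImage's independent implementation.

### Shape features

Coordinates are 0-based at pixel centers, x rightward, y downward.
Features of a blob:

* **Area** is the pixel count (times scale² when calibrated).
* **Perimeter** is the Moore-traced outer contour length with Kulpa
  chain-code weights (0.948 per axial step, 1.340 per diagonal step).
  This estimator was chosen because compactness must be ~1 for discs:
  raw boundary-pixel counting biases digitized discs to C ≈ 1.27, naive
  1/√2 chain weights to C ≈ 1.11, while the weighted chain lands within
  about 1% (the feature tests measure the disc bias explicitly).
  Single-pixel blobs get the circle-equivalent perimeter $2\sqrt{\pi}$.
* **Angle** is the principal-axis orientation from second central
  moments, measured counter-clockwise from the horizontal with y taken
  upward, in [0°, 180°). Isotropic masks (e.g. squares) have no principal
  axis; they report 0° with a degeneracy flag.
* **Length** is the full extent of the mask along the principal axis
  (rotated-bounding-box length, pixel-center extent + 1), matching the
  "floral length" usage for elongated organs.
* **Compactness** is $C=p^2/(4\pi A)$: exactly 1 for an analytic circle,
  larger for elongated or irregular shapes.

Derived series: the **motion vector** $MV_i=\sqrt{(cx_i-cx_o)^2+(cy_i-cy_o)^2}$
against the first-frame centroid (its variance is the organ's activity
score), and **growth velocity** $v_j=(l_{j+1}-l_j)/\Delta t$, a forward
difference that may legitimately be negative when an organ turns toward
the camera.

## Adaptive ROI tracking

The tracker keeps the rectangle circumscribing the tracked blob (RC) and
expands it outward by margins MGX/MGY — the maximum expected growth plus
displacement per capture interval along each axis — clamping at the image
bounds. Per frame: segment inside the current ROI, select the blob
(largest area; when several areas are within 10% of the largest, nearest
centroid to the previous frame), recompute RC and the ROI. The printed
vertex expressions the design follows contain sign inconsistencies across
the four corners; the evident intent — symmetric outward expansion by
(MGX, MGY) — is what is implemented. If the ROI comes up empty, one
full-frame re-segmentation picks the blob nearest the last known centroid
(an organ can exit a clamped ROI); frames that still fail are flagged
missing, never interpolated. The ROI follows RC both ways, so it also
shrinks for senescing organs. The containment guarantee — the organ never
truncated while its per-frame growth and displacement stay within the
margins — is exercised on synthetic sequences in the test suite.

## Transition correction

Let $V_j$ be any pixel-counting variable sampled along the schedule, with
$n$ samples per night and $d$ per day. At a night→day transition the
observed step is $K_1=V_{n+1}-V_n$ while the mean within-night step is
$K_2=\frac{1}{n-1}\sum(V_{j+1}-V_j)$; $K_3$/$K_4$ are the day-side
analogues. Applied literally as printed ("$V_j+K_1+K_2$"), the correction
would *enlarge* the discontinuity it is meant to remove, so the package
implements the contract the figures show: at each transition, taken in
time order, every subsequent sample is offset by $-K_\text{jump}+K_\text{period}$
(subtract the observed jump, restore the mean step of the period that just
ended), with offsets accumulating across transitions. Consequences, both
tested: within-period successive differences are untouched (exactly, up to
the ~1e-14 relative rounding of one constant addition), and the corrected
series' transition steps are period-step-sized rather than jump-sized.
Correction is forward-only — samples before a transition are never
revisited — and a transition with no preceding period (the schedule's
first instant) is skipped. Periods need at least 2 samples, otherwise the
mean step is undefined and the offending period is named in the error.

**Accumulated growth** sums positive increments only, anchored at 0, so
apparent shrinkage (orientation changes, not tissue loss) never reduces
the total. **Binary growth patterns** split the accumulated area and
length series into blocks of `samplesPerInterval` samples (8 h = 48
samples at 6 images/hour; 21 intervals for a 7-day run) and flag a block
1 when the series rises by more than 1% (configurable) of its total
range — the epsilon guards against noise-driven false positives.
Intervals flagged for length but not area expose the decoupling of
proximo-distal versus lateral growth.

**Organ ranking** applies the three organ-selection criteria: visibility
(fraction of frames with a valid measurement, default minimum 0.8),
occlusion (fraction of frames with >50% bounding-box overlap by another
organ, default maximum 0.5; worse organs are discarded), and activity
(motion-vector variance) to rank the survivors for nutation studies.

## Metric calibration

The target is a grid of 100 circles (ten columns, ten rows), radius 5 mm,
with 10 mm separation between circles. Separation is read as the
edge-to-edge gap — a 10 mm *center* pitch would make 5 mm-radius circles
touch and merge into one blob — giving a 20 mm center-to-center pitch,
enforced by the target's validity check (`pitch > 2 x radius`).
Detection reuses the segmentation chain: Otsu threshold with automatic
polarity (circles are the minority class), 8-connected components,
circle-likeness filtering (compactness ≤ 1.3), intensity-weighted
centroids, and row-major ordering by clustering center y-coordinates.
`scale_x` is pitch divided by the mean horizontal center spacing
(`scale_y` analogous; anisotropy is allowed since CCIR video pixels need
not be square), and the residual is the RMS deviation from the ideal grid
after a least-squares similarity fit. The capture volume is calibrated as
a stack of planes (typically 50, 10 mm apart); queries at intermediate
sample distances interpolate linearly between the two bracketing planes
and refuse to extrapolate. Lens distortion is ignored — no distortion
model is available for the chamber optics — and only a scale (not a full
homography) is stored per plane.

## The synthetic chamber

The simulator renders a single bright organ — a rotated ellipse or
superellipse — whose semi-axes grow linearly per frame (separately in x
and y, so area and length growth can decouple), whose centroid nutates
sinusoidally along the vertical axis, and whose orientation may drift.
Rasterization is an analytic point-in-boundary test at pixel centers with
no anti-aliasing, so the ground-truth pixel area is exactly countable and
is recorded alongside the closed-form area, centroid, semi-axes, angle and
perimeter per frame. Nutation starts at a trough (dawn at an extreme), so
the peak-to-origin swing over a full period is twice the amplitude. A
dawn-pulse mode adds a cumulative step in position/angle at each
night→day transition, emulating the fast post-dawn movements some flowers
show. Noise is additive Gaussian, clipped to [0, 255]; all randomness
flows from a single integer seed and sequences are bitwise reproducible.

**Why the day/night jump is modelled geometrically.** With hard-edged
analytic blobs, changing only the gray levels between periods cannot move
any pixel-counting measurement — every thresholding method recovers the
same mask, and there would be nothing for the transition correction to
correct. The real artifacts come from using two cameras: they sit a few
millimetres apart on the vertical axis, and the night camera (no
polarizing filter, higher far-red sensitivity) blooms bright outlines.
The illumination model therefore exposes `nightShiftPx` (default 4 px
vertical offset of night frames) and `nightBloomPx` (default 1 px outline
dilation in night frames). Ground truth always records the true geometry,
so tracked night-frame series show genuine centroid and area steps at
every transition — which the correction must, and in the tests does,
remove.

**Defaults as study conditions.** The default experiment mirrors the
reference cladode run: 7 days, 16 h/8 h photoperiod, 6 images/hour (1,008
frames — the same arithmetic gives 2,160 for 15 days). No quantitative
nutation amplitude is available for the emulated flowers, so the organ
defaults are chosen once as plausible for a flower limb at the reference
optics: 30 x 20 px initial semi-axes, 0.05 px/frame semi-axis growth,
4 px nutation amplitude over a 24-frame period. Pipeline-level tests run
this plan at 240 x 320 px with the organ tracked by margins (8, 12) px;
unit tests use 1–2-day plans at 100–170 px frames to stay fast. The
simulator does **not** emulate photorealistic texture, occlusion between
moving organs (only static distractor discs), phototropic bending or
illumination gradients — so passing tests demonstrate the correctness of
the measurement chain, not robustness to every field condition.

## Numerical choices and edge cases

* Threshold ties: lowest optimal level (determinism).
* Foreground polarity: organ brighter than background; `invert` flag for
  the opposite case.
* Connectivity: 8-connected foreground (a diagonal pixel chain is one
  blob).
* Rectangles are (xmin, ymin, xmax, ymax), 0-based inclusive.
* Constant (untresholdable) ROI content during tracking is treated as
  "no blob found", triggering recovery, rather than as a hard error.
* Degenerate inputs rejected with explicit messages: empty masks,
  constant images at top-level thresholding, organs leaving the frame
  (checked analytically for the whole plan before rendering), gray levels
  outside [0, 255], day/night contrast below 20 gray levels, calibration
  grids with the wrong circle count, scale queries outside the calibrated
  range.
* Isotropic metric scaling only in `computeShape`; anisotropic plane
  scales are reported separately by the calibration module and can be
  applied per-axis to coordinate series.

## Known limitations

* The perimeter estimator is tuned for smooth convex outlines; strongly
  concave or holed organs are measured by their outer contour only.
* The transition correction assumes the within-period mean step is a good
  local estimate of true change; a transition coinciding with a genuine
  growth burst will have that burst attenuated into the period mean.
* Accumulated growth rectifies measurement noise upward by construction;
  with per-frame growth well above the rasterization jitter this bias is
  negligible (the end-to-end tests quantify it), but for near-stationary
  organs the accumulated series should be read with its epsilon in mind.
* Organ identity across frames is area/proximity-based; two similar
  organs crossing paths inside one ROI can swap tracks. The ranking
  module's occlusion criterion is the guard: such organs should be
  discarded upstream.
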