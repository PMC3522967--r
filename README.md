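# dielvision

Image analysis for plant growth-chamber time-lapse experiments run under
alternating day/night illumination. The package is aimed at chronobiology
and phenotyping labs that film growing, nutating organs — flowers,
stems, cacti cladodes — at rates of several images per hour and need
quantitative growth and movement series out of the raw frames.

It provides, as a library plus a thin `dielvision` command-line script:

* a **configurable segmentation chain** — up to four
  filtering/morphology preprocessing steps, histogram thresholding by
  Otsu, Kapur (maximum entropy) or Kittler–Illingworth (minimum error),
  8-connected blob extraction, and blob filtering by area, compactness,
  length and perimeter;
* **shape and motion descriptors**: area `A`, perimeter `p`,
  principal-axis length and angle, center of gravity `(cX, cY)`,
  compactness `C = p² / (4πA)` (1 for a circle), motion vector
  `MV_i = √((cX_i − cX_o)² + (cY_i − cY_o)²)` against the first-frame
  centroid, and growth velocity `v_j = Δl_j / Δt`;
* **adaptive-ROI tracking** that keeps a growing/moving organ inside the
  analysis window by expanding its circumscribed rectangle with growth
  margins (MGX, MGY) every frame;
* **day/night transition correction**: per transition, the observed jump
  `K1` is replaced by the mean within-period step `K2` (offset
  `−K1 + K2`, accumulating), removing the camera-switch discontinuities
  from pixel-counting series while leaving within-period dynamics
  untouched; accumulated-growth series and binary per-interval growth
  patterns are derived from the corrected series;
* **circle-grid metric calibration** (10 x 10 circles of 5 mm radius):
  per-plane mm/pixel scales with residuals, linearly interpolated across
  a stack of calibration planes;
* a **synthetic chamber simulator** rendering ground-truthed sequences —
  a growing, nutating ellipse/superellipse under day/night gray
  statistics with the two-camera transition artifacts — used throughout
  the tests to validate the chain end to end.

## Worked example

Simulate a 2-day experiment at 3 images/hour (16 h light / 8 h dark),
track the organ, correct the transitions and accumulate growth:

```r
library(dielvision)

plan  <- experimentPlan(days = 2, imagesPerHour = 3)
organ <- organModel(initialSemiaxes = c(14, 9), growthRate = c(0.06, 0.04),
                    nutationAmplitude = 3, nutationPeriod = 24,
                    baseAngle = 20, center = c(80, 60))
illum <- illuminationModel(noiseSd = 0)          # jump emulation on
sq    <- simulateSequence(organ, illum, plan, seed = 3, size = c(120, 160))
sq
#> ChamberSequence: 144 frames (96 day, 48 night), 160x120 px, seed 3

track <- trackSequence(sq, userRect = c(40, 20, 120, 100),
                       pipelineConfig(), mgx = 8, mgy = 12)
f <- trackFeatures(track)
sum(f$missing)
#> [1] 0

corrected <- correctTransitions(f$area, sq@schedule)
tix <- which(f$transition != "none")[-1]
round(abs(diff(f$area))[tix - 1], 1)     # raw area steps at the transitions
#> [1]  88  92 118
round(abs(diff(corrected))[tix - 1], 2)  # after correction: period-sized steps
#> [1] 3.83 4.70 4.94

acc   <- accumulateGrowth(corrected)
truth <- groundTruth(sq)
c(true = round(truth$areaTrue[144] - truth$areaTrue[1], 1),
  recovered = round(acc[144], 1))
#>      true recovered
#>     648.4     703.5
```

The raw area series jumps by ~100 px² at every day/night switch (the two
cameras see the organ shifted and bloomed differently); after correction
the transition steps match the organ's true per-frame growth (~4 px²).
The accumulated total slightly exceeds the analytic truth here because
positive-increment accumulation rectifies rasterization jitter on this
deliberately small organ; at the package's default organ size the
week-long tests recover total growth to well under 3%.

Metric calibration:

```r
target <- calibrationTarget()                        # 10x10, r = 5 mm
g   <- renderCalibrationGrid(target, scaleMmPerPx = 0.25)
cen <- detectGridCircles(g$image, target)
fitPlaneScale(cen, target, distanceMm = 100)
#> PlaneCalibration @ 100 mm: scale (0.25000, 0.25000) mm/px, residual 0.0000 mm
```

The same flows are available from the shell via `exec/dielvision`
(`simulate`, `calibrate`, `analyze`, `correct`, `rhythm` subcommands; see
the script header for options).

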