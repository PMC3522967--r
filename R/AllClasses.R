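#' @import methods
NULL

#' Experiment plan for a growth-chamber capture run
#'
#' Holds the day/night timing program of a capture experiment: start and end
#' times, photoperiod split (day + night hours must total 24), capture rate,
#' the night-flash and panel pre-switch timings (carried for logging; they do
#' not move capture instants), the image format and the camera-to-sample
#' distance used for metric calibration.
#'
#' @slot tStart,tEnd experiment start/end (`POSIXct`, naive local time).
#' @slot dayHours,nightHours photoperiod split in hours; must sum to 24.
#' @slot imagesPerHour capture rate, images per hour (>= 1).
#' @slot nightFlashSeconds duration the far-red night panel is switched on
#'   around each night capture (seconds, > 0).
#' @slot preSwitchSeconds panel pre-switch lead time (seconds, >= 0).
#' @slot imageFormat one of `"BMP"`, `"TIFF"`, `"JPG"`, `"PNG"`.
#' @slot sampleDistanceMm camera-to-sample distance in mm (NA if unused).
#' @exportClass ExperimentPlan
setClass("ExperimentPlan",
  representation(
    tStart = "POSIXct", tEnd = "POSIXct",
    dayHours = "numeric", nightHours = "numeric",
    imagesPerHour = "numeric",
    nightFlashSeconds = "numeric", preSwitchSeconds = "numeric",
    imageFormat = "character", sampleDistanceMm = "numeric"
  )
)

setValidity("ExperimentPlan", function(object) {
  msg <- character(0)
  if (!isTRUE(all.equal(object@dayHours + object@nightHours, 24)))
    msg <- c(msg, "dayHours + nightHours must equal 24")
  if (object@dayHours <= 0 || object@nightHours <= 0)
    msg <- c(msg, "dayHours and nightHours must be positive")
  if (!(object@tEnd > object@tStart))
    msg <- c(msg, "tEnd must be after tStart")
  if (object@imagesPerHour < 1)
    msg <- c(msg, "imagesPerHour must be >= 1")
  if (!is.na(object@nightFlashSeconds) && object@nightFlashSeconds <= 0)
    msg <- c(msg, "nightFlashSeconds must be > 0")
  if (!is.na(object@preSwitchSeconds) && object@preSwitchSeconds < 0)
    msg <- c(msg, "preSwitchSeconds must be >= 0")
  if (!object@imageFormat %in% c("BMP", "TIFF", "JPG", "PNG"))
    msg <- c(msg, "imageFormat must be one of BMP, TIFF, JPG, PNG")
  if (length(msg)) msg else TRUE
})

#' Capture schedule derived from an experiment plan
#'
#' The ordered list of capture instants, each labelled with the illumination
#' period active at that instant (`day`/`night`) and a transition flag:
#' `T_nd` on the first instant of every day period, `T_dn` on the first
#' instant of every night period, `none` elsewhere.  Instants are strictly
#' increasing and evenly spaced at 60/imagesPerHour minutes.
#'
#' @slot instants capture times (`POSIXct`).
#' @slot period `"day"` or `"night"` per instant.
#' @slot transition `"none"`, `"T_nd"` or `"T_dn"` per instant.
#' @slot plan the originating [ExperimentPlan-class].
#' @exportClass CaptureSchedule
setClass("CaptureSchedule",
  representation(instants = "POSIXct", period = "character",
                 transition = "character", plan = "ExperimentPlan")
)

setValidity("CaptureSchedule", function(object) {
  n <- length(object@instants)
  msg <- character(0)
  if (length(object@period) != n || length(object@transition) != n)
    msg <- c(msg, "period/transition must match instants in length")
  if (n > 1 && any(diff(as.numeric(object@instants)) <= 0))
    msg <- c(msg, "instants must be strictly increasing")
  fl <- object@transition[object@transition != "none"]
  if (length(fl) > 1 && any(fl[-1] == fl[-length(fl)]))
    msg <- c(msg, "transition flags must alternate T_nd/T_dn")
  if (length(msg)) msg else TRUE
})

#' Geometric model of a single synthetic plant organ
#'
#' Describes a bright organ blob (flower limb or cladode stand-in) as a
#' rotated ellipse or superellipse whose semi-axes grow linearly per frame,
#' whose centroid nutates sinusoidally along the vertical image axis, and
#' whose orientation may drift.  A dawn-pulse mode adds a step change in
#' position/angle at every night-to-day transition, emulating the fast
#' movement some flowers show shortly after dawn.
#'
#' @slot shapeKind `"ellipse"` or `"superellipse"`.
#' @slot initialSemiaxes `(a, b)` semi-axes at frame 0 in pixels.
#' @slot growthRate `(gx, gy)` semi-axis growth in pixels/frame (may differ,
#'   so length and area growth can decouple).
#' @slot nutationAmplitude sinusoidal centroid displacement amplitude (px).
#' @slot nutationPeriod nutation period in frames.
#' @slot baseAngle principal-axis angle at frame 0, degrees CCW from the
#'   horizontal (y measured upward).
#' @slot angleDrift degrees/frame added to the angle.
#' @slot exponent superellipse exponent (2 = ellipse).
#' @slot center organ centre `(x, y)` in pixels, or `NA` for frame centre.
#' @slot dawnPulsePx,dawnPulseDeg step in vertical position / angle applied
#'   cumulatively at each night-to-day transition (0 disables).
#' @exportClass OrganModel
setClass("OrganModel",
  representation(
    shapeKind = "character", initialSemiaxes = "numeric",
    growthRate = "numeric", nutationAmplitude = "numeric",
    nutationPeriod = "numeric", baseAngle = "numeric",
    angleDrift = "numeric", exponent = "numeric", center = "numeric",
    dawnPulsePx = "numeric", dawnPulseDeg = "numeric"
  )
)

setValidity("OrganModel", function(object) {
  msg <- character(0)
  if (!object@shapeKind %in% c("ellipse", "superellipse"))
    msg <- c(msg, "shapeKind must be 'ellipse' or 'superellipse'")
  if (length(object@initialSemiaxes) != 2 || any(object@initialSemiaxes <= 0))
    msg <- c(msg, "initialSemiaxes must be two positive numbers")
  if (length(object@growthRate) != 2)
    msg <- c(msg, "growthRate must have length 2")
  if (object@nutationAmplitude < 0)
    msg <- c(msg, "nutationAmplitude must be >= 0")
  if (object@nutationPeriod <= 0)
    msg <- c(msg, "nutationPeriod must be > 0")
  if (object@exponent < 1)
    msg <- c(msg, "exponent must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Day/night illumination statistics of the synthetic chamber
#'
#' Gray-level statistics of the two capture periods plus the imaging
#' artifacts of a two-camera day/night rig: the night camera may see the
#' scene shifted vertically (the cameras sit a few mm apart on the vertical
#' axis) and may bloom the bright organ outline (no filter, higher far-red
#' sensitivity).  Those artifacts are what make pixel-counting measurements
#' jump at period transitions; with `jumpEmulation = FALSE` night frames use
#' the day geometry and only the gray levels switch.
#'
#' @slot dayBg,dayFg,nightBg,nightFg background/foreground gray levels
#'   (0-255); contrast must be >= 20 gray levels in each period.
#' @slot noiseSd additive Gaussian noise SD in gray levels (clipped 0-255).
#' @slot jumpEmulation logical; emulate the two-camera artifacts.
#' @slot nightShiftPx vertical shift of night frames, pixels.
#' @slot nightBloomPx outline bloom of the organ in night frames, pixels.
#' @exportClass IlluminationModel
setClass("IlluminationModel",
  representation(
    dayBg = "numeric", dayFg = "numeric",
    nightBg = "numeric", nightFg = "numeric",
    noiseSd = "numeric", jumpEmulation = "logical",
    nightShiftPx = "numeric", nightBloomPx = "numeric"
  )
)

setValidity("IlluminationModel", function(object) {
  lv <- c(object@dayBg, object@dayFg, object@nightBg, object@nightFg)
  msg <- character(0)
  if (any(lv < 0 | lv > 255))
    msg <- c(msg, "gray levels must lie within [0, 255]")
  if (abs(object@dayFg - object@dayBg) < 20)
    msg <- c(msg, "day foreground/background contrast must be >= 20 gray levels")
  if (abs(object@nightFg - object@nightBg) < 20)
    msg <- c(msg, "night foreground/background contrast must be >= 20 gray levels")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@nightShiftPx < 0 || object@nightBloomPx < 0)
    msg <- c(msg, "nightShiftPx and nightBloomPx must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A rendered synthetic time-lapse sequence with ground truth
#'
#' One frame per scheduled capture instant plus the analytic per-frame ground
#' truth (true area, centroid, semi-axes, angle, perimeter) of the rendered
#' organ.  Deterministic given the seed.
#'
#' @slot frames list of 8-bit grayscale images (integer matrices, `[y, x]`).
#' @slot schedule the [CaptureSchedule-class] the frames follow.
#' @slot truth data frame, one row per frame (see [simulateSequence]).
#' @slot organ,illum the generating models.
#' @slot seed integer seed the sequence was rendered with.
#' @exportClass ChamberSequence
setClass("ChamberSequence",
  representation(frames = "list", schedule = "CaptureSchedule",
                 truth = "data.frame", organ = "OrganModel",
                 illum = "IlluminationModel", seed = "numeric")
)

setValidity("ChamberSequence", function(object) {
  if (length(object@frames) != nrow(object@truth))
    return("one ground-truth record per rendered frame required")
  gr <- object@organ@growthRate
  if (all(gr >= 0) && is.unsorted(object@truth$areaTrue))
    return("true area must be monotone non-decreasing when both growth rates are >= 0")
  TRUE
})

#' Circle-grid calibration target geometry
#'
#' A printed grid of `rows x cols` circles used for metric calibration.
#' `pitchMm` is the center-to-center separation and must exceed the circle
#' diameter so the circles stay disjoint.
#'
#' @slot rows,cols grid dimensions (default 10 x 10, i.e. 100 circles).
#' @slot circleRadiusMm circle radius in mm (default 5).
#' @slot pitchMm center-to-center separation in mm (default 20, i.e. a
#'   10 mm gap between 5 mm-radius circles).
#' @exportClass CalibrationTarget
setClass("CalibrationTarget",
  representation(rows = "numeric", cols = "numeric",
                 circleRadiusMm = "numeric", pitchMm = "numeric")
)

setValidity("CalibrationTarget", function(object) {
  msg <- character(0)
  if (object@rows < 2 || object@cols < 2)
    msg <- c(msg, "at least a 2x2 grid is required")
  if (object@circleRadiusMm <= 0) msg <- c(msg, "circleRadiusMm must be > 0")
  if (object@pitchMm <= 2 * object@circleRadiusMm)
    msg <- c(msg, "pitchMm must exceed the circle diameter (non-overlapping circles)")
  if (length(msg)) msg else TRUE
})

#' Pixel-to-mm calibration of one camera plane
#'
#' @slot distanceMm distance from the camera to the calibrated plane.
#' @slot scaleX,scaleY mm per pixel along x/y (anisotropy permitted; CCIR
#'   video pixels need not be square).
#' @slot residualMm RMS deviation of the detected centers from the ideal
#'   grid after a least-squares similarity fit, in mm.
#' @exportClass PlaneCalibration
setClass("PlaneCalibration",
  representation(distanceMm = "numeric", scaleX = "numeric",
                 scaleY = "numeric", residualMm = "numeric")
)

setValidity("PlaneCalibration", function(object) {
  if (object@scaleX <= 0 || object@scaleY <= 0)
    return("scaleX and scaleY must be > 0")
  if (object@residualMm < 0) return("residualMm must be >= 0")
  TRUE
})

#' Multi-plane calibration model
#'
#' Ordered per-plane pixel-to-mm scales covering the capture volume (the
#' chamber volume is sliced into parallel planes, typically 50 planes 10 mm
#' apart).  Scale queries between planes are linearly interpolated; queries
#' outside the covered range are refused.
#'
#' @slot planes data frame with columns `distanceMm`, `scaleX`, `scaleY`,
#'   `residualMm`, sorted by strictly increasing distance.
#' @exportClass CalibrationModel
setClass("CalibrationModel", representation(planes = "data.frame"))

setValidity("CalibrationModel", function(object) {
  p <- object@planes
  need <- c("distanceMm", "scaleX", "scaleY", "residualMm")
  if (!all(need %in% names(p)))
    return("planes must have columns distanceMm, scaleX, scaleY, residualMm")
  if (nrow(p) < 1) return("at least one plane required")
  if (any(diff(p$distanceMm) <= 0))
    return("plane distances must be strictly increasing")
  if (any(p$scaleX <= 0 | p$scaleY <= 0)) return("scales must be > 0")
  TRUE
})

#' Segmentation pipeline configuration
#'
#' The configurable preprocessing -> thresholding -> blob filtering chain.
#' Preprocessing is an ordered list of at most four operations, each a list
#' with `op` (one of `average`, `median`, `laplacian`, `sharpen`,
#' `custom_mask`, `dilation`, `erosion`, `opening`, `closing`), `size`
#' (odd kernel size), `iterations` (>= 1) and, for `custom_mask`, `mask`
#' (odd-sized 3x3/5x5/7x7 matrix).
#'
#' @slot preprocessing ordered op list (length <= 4).
#' @slot edgeDetector `"none"`, `"roberts"` or `"sobel"` (optional
#'   preprocessing for kinky organ outlines; segmentation still proceeds via
#'   thresholding).
#' @slot thresholdMethod `"otsu"`, `"kapur"`, `"kittler"` or `"fixed"`.
#' @slot fixedLevel level for `"fixed"` (foreground = pixels > level).
#' @slot invert invert gray levels before thresholding (organ darker than
#'   background); default polarity is organ brighter.
#' @slot blobFilters named list of bounds among `areaMin`, `areaMax`,
#'   `compactnessMin`, `compactnessMax`, `lengthMin`, `lengthMax`,
#'   `perimeterMin`, `perimeterMax`.
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(preprocessing = "list", edgeDetector = "character",
                 thresholdMethod = "character", fixedLevel = "numeric",
                 invert = "logical", blobFilters = "list")
)

setValidity("PipelineConfig", function(object) {
  msg <- character(0)
  if (length(object@preprocessing) > 4)
    msg <- c(msg, "at most 4 preprocessing operations are allowed")
  okOps <- c("average", "median", "laplacian", "sharpen", "custom_mask",
             "dilation", "erosion", "opening", "closing")
  for (op in object@preprocessing) {
    if (!is.list(op) || is.null(op$op) || !op$op %in% okOps) {
      msg <- c(msg, "each preprocessing entry needs a valid $op"); next
    }
    it <- if (is.null(op$iterations)) 1L else op$iterations
    if (it < 1) msg <- c(msg, "iteration counts must be >= 1")
    if (identical(op$op, "custom_mask")) {
      if (is.null(op$mask) || !is.matrix(op$mask) ||
          any(dim(op$mask) %% 2 == 0) ||
          !all(dim(op$mask) %in% c(3, 5, 7)))
        msg <- c(msg, "custom_mask requires an odd 3x3, 5x5 or 7x7 matrix")
    } else if (!is.null(op$size) && op$size %% 2 == 0) {
      msg <- c(msg, "kernel sizes must be odd")
    }
  }
  if (!object@edgeDetector %in% c("none", "roberts", "sobel"))
    msg <- c(msg, "edgeDetector must be none, roberts or sobel")
  if (!object@thresholdMethod %in% c("otsu", "kapur", "kittler", "fixed"))
    msg <- c(msg, "thresholdMethod must be otsu, kapur, kittler or fixed")
  bf <- object@blobFilters
  okF <- c("areaMin", "areaMax", "compactnessMin", "compactnessMax",
           "lengthMin", "lengthMax", "perimeterMin", "perimeterMax")
  if (length(bf) && (is.null(names(bf)) || !all(names(bf) %in% okF)))
    msg <- c(msg, "unknown blob filter name")
  for (q in c("area", "compactness", "length", "perimeter")) {
    lo <- bf[[paste0(q, "Min")]]; hi <- bf[[paste0(q, "Max")]]
    if (!is.null(lo) && !is.null(hi) && lo > hi)
      msg <- c(msg, sprintf("%s filter has min > max", q))
  }
  if (length(msg)) msg else TRUE
})

#' Adaptive region-of-interest tracker state
#'
#' The current analysis window of the adaptive-ROI tracker: the rectangle
#' circumscribing the last accepted blob (`rc`) expanded outward by the
#' growth margins `mgx`/`mgy` (the maximum expected growth plus displacement
#' per capture interval along x/y) and clamped to the image bounds.
#' Rectangles are `(xmin, ymin, xmax, ymax)`, 0-based inclusive pixel
#' coordinates.
#'
#' @slot roi current ROI rectangle.
#' @slot rc circumscribed rectangle of the last accepted blob.
#' @slot mgx,mgy growth margins in pixels (>= 0).
#' @slot bounds image size `(H, W)`.
#' @slot lastCentroid centroid `(cx, cy)` of the last accepted blob.
#' @slot lastArea area of the last accepted blob (px^2).
#' @exportClass AROIState
setClass("AROIState",
  representation(roi = "numeric", rc = "numeric", mgx = "numeric",
                 mgy = "numeric", bounds = "numeric",
                 lastCentroid = "numeric", lastArea = "numeric")
)

setValidity("AROIState", function(object) {
  if (object@mgx < 0 || object@mgy < 0) return("mgx and mgy must be >= 0")
  r <- object@roi
  if (r[1] > r[3] || r[2] > r[4]) return("degenerate ROI rectangle")
  TRUE
})

#' Per-organ track across a frame sequence
#'
#' Per-frame shape features and ROI rectangles for one tracked organ.
#' Frames where the organ could not be recovered are flagged missing, never
#' interpolated.
#'
#' @slot features data frame, one row per frame: `frame`, `instant`,
#'   `period`, `transition`, `area`, `perimeter`, `length`, `angle`, `cx`,
#'   `cy`, `compactness`, `missing`.
#' @slot rois matrix (frames x 4) of ROI rectangles.
#' @slot mgx,mgy margins used.
#' @slot config the [PipelineConfig-class] used.
#' @exportClass OrganTrack
setClass("OrganTrack",
  representation(features = "data.frame", rois = "matrix",
                 mgx = "numeric", mgy = "numeric", config = "PipelineConfig")
)

setValidity("OrganTrack", function(object) {
  if (nrow(object@features) != nrow(object@rois))
    return("one ROI per tracked frame required")
  TRUE
})

#' Binary diel growth pattern
#'
#' Per-interval binary growth flags for accumulated area and length: 1 when
#' the accumulated series increased over the interval by more than epsilon
#' (a fraction of the series' total range), 0 otherwise.
#'
#' @slot flags data frame with columns `interval`, `area`, `length` (0/1).
#' @slot samplesPerInterval capture samples per interval.
#' @slot epsilon absolute growth threshold used, in series units, per series
#'   (named numeric: `area`, `length`).
#' @exportClass GrowthPattern
setClass("GrowthPattern",
  representation(flags = "data.frame", samplesPerInterval = "numeric",
                 epsilon = "numeric")
)

setValidity("GrowthPattern", function(object) {
  f <- object@flags
  if (!all(c("interval", "area", "length") %in% names(f)))
    return("flags must have columns interval, area, length")
  if (!all(unlist(f[c("area", "length")]) %in% c(0, 1)))
    return("flags must be 0/1")
  TRUE
})
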