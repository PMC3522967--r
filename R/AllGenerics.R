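#' @include AllClasses.R
NULL

#' Total number of images a plan generates
#'
#' The number of images of a capture experiment is
#' days x images/hour x 24.  A 7-day experiment at 6 images/hour yields
#' 1,008 images; 15 days at 6/hour yield 2,160.  For plans spanning a
#' non-integral number of days the count is computed on fractional hours:
#' `floor(total hours x images/hour)`.
#'
#' @param plan an [ExperimentPlan-class].
#' @return integer image count.
#' @examples
#' p <- experimentPlan(days = 7, imagesPerHour = 6)
#' countImages(p)  # 1008
#' @export
setGeneric("countImages", function(plan) standardGeneric("countImages"))

#' Build the capture schedule of a plan
#'
#' Evenly spaced capture instants at 60/imagesPerHour-minute intervals over
#' `[tStart, tEnd)`, each labelled with the active illumination period.
#' The phase is anchored at `tStart` = dawn (lights-on); instants on a
#' period boundary belong to the period that begins there.  The first
#' instant of every period carries a transition flag (`T_nd` entering day,
#' `T_dn` entering night).
#'
#' @param plan an [ExperimentPlan-class].
#' @return a [CaptureSchedule-class].
#' @export
setGeneric("buildSchedule", function(plan) standardGeneric("buildSchedule"))

#' Interpolate the pixel-to-mm scale at a sample distance
#'
#' Linear interpolation between the two calibrated planes bracketing
#' `distanceMm`; an exact plane distance returns that plane's scales.  No
#' extrapolation: distances outside the covered range are an error.
#'
#' @param model a [CalibrationModel-class].
#' @param distanceMm camera-to-sample distance in mm.
#' @return named numeric `c(scaleX = , scaleY = )` in mm/pixel.
#' @export
setGeneric("scaleAtDistance",
           function(model, distanceMm) standardGeneric("scaleAtDistance"))

#' Per-frame feature table of a track or sequence ground truth
#'
#' @param x an [OrganTrack-class] or [ChamberSequence-class].
#' @return a data frame with one row per frame.
#' @export
setGeneric("trackFeatures", function(x) standardGeneric("trackFeatures"))

#' Ground-truth table of a synthetic sequence
#' @param x a [ChamberSequence-class].
#' @return data frame, one row per rendered frame.
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' Frames of a synthetic sequence
#' @param x a [ChamberSequence-class].
#' @return list of integer matrices.
#' @export
setGeneric("chamberFrames", function(x) standardGeneric("chamberFrames"))

#' Schedule table
#' @param x a [CaptureSchedule-class] or [ChamberSequence-class].
#' @return data frame with columns `instant`, `period`, `transition`.
#' @export
setGeneric("scheduleTable", function(x) standardGeneric("scheduleTable"))

#' Calibrated planes of a model
#' @param x a [CalibrationModel-class].
#' @return data frame of per-plane scales.
#' @export
setGeneric("calibrationPlanes", function(x) standardGeneric("calibrationPlanes"))

#' Binary flag table of a growth pattern
#' @param x a [GrowthPattern-class].
#' @return data frame with columns `interval`, `area`, `length`.
#' @export
setGeneric("patternFlags", function(x) standardGeneric("patternFlags"))

#' Current ROI rectangle of a tracker state
#' @param x an [AROIState-class].
#' @return numeric `(xmin, ymin, xmax, ymax)`, 0-based inclusive.
#' @export
setGeneric("currentRoi", function(x) standardGeneric("currentRoi"))
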