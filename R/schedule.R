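#' @include AllClasses.R AllGenerics.R
NULL

#' Create an experiment plan
#'
#' Constructor for [ExperimentPlan-class].  Either give `tStart`/`tEnd`
#' explicitly or a number of whole `days` from `tStart` (default start
#' 2000-01-01 00:00, a naive local time; the package does no timezone or
#' DST handling).
#'
#' @param tStart,tEnd start and end of the experiment (`POSIXct` or
#'   anything `as.POSIXct` accepts).
#' @param days convenience: experiment length in days when `tEnd` is
#'   missing.
#' @param dayHours,nightHours photoperiod split (must sum to 24); default
#'   16 h light / 8 h dark.
#' @param imagesPerHour capture rate (>= 1).
#' @param nightFlashSeconds far-red night-panel on-time per night capture
#'   (logged; does not alter capture instants).
#' @param preSwitchSeconds panel pre-switch lead time (logged only).
#' @param imageFormat `"PNG"` (default), `"TIFF"`, `"JPG"` or `"BMP"`.
#' @param sampleDistanceMm camera-to-sample distance for calibration.
#' @return an [ExperimentPlan-class].
#' @examples
#' experimentPlan(days = 7, imagesPerHour = 6)
#' @export
experimentPlan <- function(tStart = "2000-01-01 00:00:00", tEnd = NULL,
                           days = NULL, dayHours = 16, nightHours = 8,
                           imagesPerHour = 1, nightFlashSeconds = 2,
                           preSwitchSeconds = 0, imageFormat = "PNG",
                           sampleDistanceMm = NA_real_) {
  tStart <- as.POSIXct(tStart, tz = "UTC")
  if (is.null(tEnd)) {
    if (is.null(days)) stop("give either tEnd or days")
    tEnd <- tStart + days * 86400
  } else {
    tEnd <- as.POSIXct(tEnd, tz = "UTC")
  }
  new("ExperimentPlan", tStart = tStart, tEnd = tEnd,
      dayHours = dayHours, nightHours = nightHours,
      imagesPerHour = imagesPerHour,
      nightFlashSeconds = nightFlashSeconds,
      preSwitchSeconds = preSwitchSeconds,
      imageFormat = toupper(imageFormat),
      sampleDistanceMm = sampleDistanceMm)
}

planHours <- function(plan) {
  as.numeric(difftime(plan@tEnd, plan@tStart, units = "hours"))
}

#' @rdname countImages
setMethod("countImages", "ExperimentPlan", function(plan) {
  h <- planHours(plan)
  # whole-day spans reduce to days x imagesPerHour x 24
  as.integer(floor(h * plan@imagesPerHour + 1e-9))
})

#' Label timestamps with their illumination period
#'
#' Deterministic day/night label per timestamp, phase anchored at the plan
#' start = dawn.  Period boundaries are half-open: a timestamp exactly on a
#' boundary belongs to the period that begins there (`tStart + dayHours` is
#' night, `tStart + 24 h` is day again).
#'
#' @param timestamps `POSIXct` (or coercible) times within
#'   `[tStart, tEnd]`.
#' @param plan an [ExperimentPlan-class].
#' @return character vector of `"day"`/`"night"`.
#' @export
labelPeriods <- function(timestamps, plan) {
  timestamps <- as.POSIXct(timestamps, tz = "UTC")
  h <- as.numeric(difftime(timestamps, plan@tStart, units = "hours"))
  if (any(h < -1e-9) || any(h > planHours(plan) + 1e-9))
    stop("timestamp outside the plan interval")
  phase <- h %% 24
  ifelse(phase < plan@dayHours - 1e-9, "day", "night")
}

#' @rdname buildSchedule
setMethod("buildSchedule", "ExperimentPlan", function(plan) {
  n <- countImages(plan)
  if (n == 0) {
    return(new("CaptureSchedule",
               instants = plan@tStart[0], period = character(0),
               transition = character(0), plan = plan))
  }
  stepSec <- 3600 / plan@imagesPerHour
  instants <- plan@tStart + (seq_len(n) - 1) * stepSec
  period <- labelPeriods(instants, plan)
  trans <- rep("none", n)
  newPeriod <- c(TRUE, period[-1] != period[-n])
  trans[newPeriod] <- ifelse(period[newPeriod] == "day", "T_nd", "T_dn")
  new("CaptureSchedule", instants = instants, period = period,
      transition = trans, plan = plan)
})

#' @rdname scheduleTable
setMethod("scheduleTable", "CaptureSchedule", function(x) {
  data.frame(instant = x@instants, period = x@period,
             transition = x@transition)
})

setMethod("length", "CaptureSchedule", function(x) length(x@instants))

setMethod("show", "ExperimentPlan", function(object) {
  cat(sprintf(
    "ExperimentPlan: %s -> %s\n  photoperiod %g h day / %g h night, %g images/hour (%d images)\n",
    format(object@tStart), format(object@tEnd), object@dayHours,
    object@nightHours, object@imagesPerHour, countImages(object)))
})

setMethod("show", "CaptureSchedule", function(object) {
  n <- length(object@instants)
  cat(sprintf(
    "CaptureSchedule: %d instants (%d day, %d night), %d transitions\n",
    n, sum(object@period == "day"), sum(object@period == "night"),
    sum(object@transition != "none")))
})

#' Read an experiment plan from a YAML or JSON config file
#'
#' The file holds a mapping with any of the [experimentPlan] arguments
#' (`tStart`, `tEnd`, `days`, `dayHours`, `nightHours`, `imagesPerHour`,
#' `nightFlashSeconds`, `preSwitchSeconds`, `imageFormat`,
#' `sampleDistanceMm`), either at the top level or under a `plan:` key.
#'
#' @param path file path (`.yaml`/`.yml`/`.json`).
#' @return an [ExperimentPlan-class].
#' @export
readPlan <- function(path) {
  cfg <- readConfigFile(path)
  if (!is.null(cfg$plan)) cfg <- cfg$plan
  do.call(experimentPlan, cfg)
}

readConfigFile <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}

#' Export a capture schedule as CSV
#'
#' One row per capture instant with columns `instant`, `period`,
#' `transition`.
#'
#' @param schedule a [CaptureSchedule-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeScheduleCsv <- function(schedule, path) {
  df <- scheduleTable(schedule)
  df$instant <- format(df$instant, "%Y-%m-%d %H:%M:%S")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a schedule CSV written by [writeScheduleCsv]
#' @param path CSV path.
#' @param plan the plan the schedule belongs to (optional; a permissive
#'   1-day default is attached when omitted).
#' @return a [CaptureSchedule-class].
#' @export
readScheduleCsv <- function(path, plan = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  inst <- as.POSIXct(df$instant, tz = "UTC")
  if (is.null(plan)) {
    plan <- experimentPlan(tStart = min(inst),
                           tEnd = max(inst) + 1, imagesPerHour = 1)
  }
  new("CaptureSchedule", instants = inst, period = df$period,
      transition = df$transition, plan = plan)
}
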