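#' @include AllClasses.R AllGenerics.R schedule.R
NULL

#' Create a synthetic organ model
#'
#' See [OrganModel-class] for the meaning of each parameter.  Defaults
#' describe a flower-limb-like bright blob: a 30 x 20 px ellipse growing
#' 0.05 px/frame per semi-axis, nutating sinusoidally with 4 px amplitude
#' over a 24-frame period, oriented 30 degrees above horizontal.
#'
#' @param shapeKind `"ellipse"` (default) or `"superellipse"`.
#' @param initialSemiaxes `(a, b)` px.
#' @param growthRate `(gx, gy)` px/frame.
#' @param nutationAmplitude px.
#' @param nutationPeriod frames.
#' @param baseAngle,angleDrift degrees, degrees/frame.
#' @param exponent superellipse exponent (2 = ellipse).
#' @param center `(x, y)` px or `NULL` for the frame centre.
#' @param dawnPulsePx,dawnPulseDeg cumulative step in vertical position /
#'   angle at each night-to-day transition.
#' @return an [OrganModel-class].
#' @export
organModel <- function(shapeKind = "ellipse", initialSemiaxes = c(30, 20),
                       growthRate = c(0.05, 0.05), nutationAmplitude = 4,
                       nutationPeriod = 24, baseAngle = 30, angleDrift = 0,
                       exponent = 2, center = NULL, dawnPulsePx = 0,
                       dawnPulseDeg = 0) {
  new("OrganModel", shapeKind = shapeKind, initialSemiaxes = initialSemiaxes,
      growthRate = growthRate, nutationAmplitude = nutationAmplitude,
      nutationPeriod = nutationPeriod, baseAngle = baseAngle,
      angleDrift = angleDrift, exponent = exponent,
      center = if (is.null(center)) c(NA_real_, NA_real_) else center,
      dawnPulsePx = dawnPulsePx, dawnPulseDeg = dawnPulseDeg)
}

#' Create an illumination model
#'
#' Defaults emulate the chamber's two periods: a bright day scene
#' (background 110, organ 200) and a darker far-red night scene
#' (background 30, organ 150), noise-free, with the two-camera transition
#' artifacts on (night frames shifted down 4 px and bloomed 1 px).
#'
#' @param dayBg,dayFg,nightBg,nightFg gray levels 0-255 (contrast >= 20
#'   per period).
#' @param noiseSd additive Gaussian noise SD (gray levels).
#' @param jumpEmulation emulate day/night measurement jumps.
#' @param nightShiftPx,nightBloomPx night-camera artifacts (px).
#' @return an [IlluminationModel-class].
#' @export
illuminationModel <- function(dayBg = 110, dayFg = 200, nightBg = 30,
                              nightFg = 150, noiseSd = 0,
                              jumpEmulation = TRUE, nightShiftPx = 4,
                              nightBloomPx = 1) {
  new("IlluminationModel", dayBg = dayBg, dayFg = dayFg, nightBg = nightBg,
      nightFg = nightFg, noiseSd = noiseSd, jumpEmulation = jumpEmulation,
      nightShiftPx = nightShiftPx, nightBloomPx = nightBloomPx)
}

setMethod("show", "OrganModel", function(object) {
  cat(sprintf(
    "OrganModel (%s): semiaxes (%g, %g) px, growth (%g, %g) px/frame,\n  nutation %g px / %g frames, angle %g deg (+%g deg/frame)\n",
    object@shapeKind, object@initialSemiaxes[1], object@initialSemiaxes[2],
    object@growthRate[1], object@growthRate[2], object@nutationAmplitude,
    object@nutationPeriod, object@baseAngle, object@angleDrift))
})

setMethod("show", "IlluminationModel", function(object) {
  cat(sprintf(
    "IlluminationModel: day bg/fg %g/%g, night bg/fg %g/%g, noise SD %g,\n  jump emulation %s (shift %g px, bloom %g px)\n",
    object@dayBg, object@dayFg, object@nightBg, object@nightFg,
    object@noiseSd, if (object@jumpEmulation) "on" else "off",
    object@nightShiftPx, object@nightBloomPx))
})

# analytic state of the organ at frame t (true geometry, no camera artifacts)
organState <- function(organ, t, size, dawnCount = 0) {
  a <- organ@initialSemiaxes[1] + organ@growthRate[1] * t
  b <- organ@initialSemiaxes[2] + organ@growthRate[2] * t
  if (a <= 0 || b <= 0) stop("organ semi-axes must stay strictly positive")
  cx <- if (is.na(organ@center[1])) (size[2] - 1) / 2 else organ@center[1]
  cy <- if (is.na(organ@center[2])) (size[1] - 1) / 2 else organ@center[2]
  # nutation starts at a trough (dawn at an extreme), so the peak-to-origin
  # swing over a full period is twice the amplitude
  cy <- cy + organ@nutationAmplitude *
    (1 - cos(2 * pi * t / organ@nutationPeriod)) +
    organ@dawnPulsePx * dawnCount
  ang <- organ@baseAngle + organ@angleDrift * t + organ@dawnPulseDeg * dawnCount
  list(a = a, b = b, cx = cx, cy = cy, angle = ang)
}

# pixel-center point-in-boundary mask of a rotated superellipse
organMask <- function(st, n, size, grow = 0, yShift = 0) {
  H <- size[1]; W <- size[2]
  a <- st$a + grow; b <- st$b + grow
  xs <- matrix(rep(0:(W - 1), each = H), H)
  ys <- matrix(rep(0:(H - 1), W), H)
  dx <- xs - st$cx
  dyu <- -(ys - (st$cy + yShift))
  th <- st$angle * pi / 180
  u <- dx * cos(th) + dyu * sin(th)
  v <- -dx * sin(th) + dyu * cos(th)
  (abs(u) / a)^n + (abs(v) / b)^n <= 1
}

superellipseArea <- function(a, b, n) {
  4 * a * b * gamma(1 + 1 / n)^2 / gamma(1 + 2 / n)
}

# Ramanujan's approximation for the ellipse; numeric quadrature fallback
# for superellipses
analyticPerimeter <- function(a, b, n) {
  if (abs(n - 2) < 1e-12) {
    h <- ((a - b) / (a + b))^2
    pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  } else {
    tt <- seq(0, pi / 2, length.out = 2001)
    x <- a * cos(tt)^(2 / n); y <- b * sin(tt)^(2 / n)
    4 * sum(sqrt(diff(x)^2 + diff(y)^2))
  }
}

checkInside <- function(st, organ, illum, size, t) {
  ext <- max(st$a, st$b) + if (illum@jumpEmulation) illum@nightBloomPx else 0
  shift <- if (illum@jumpEmulation) illum@nightShiftPx else 0
  if (st$cx - ext < 0 || st$cx + ext > size[2] - 1 ||
      st$cy - ext < 0 || st$cy + ext + shift > size[1] - 1)
    stop(sprintf(
      "organ out of frame at t=%g: extent %.1f px around (%.1f, %.1f) exceeds %dx%d image",
      t, ext, st$cx, st$cy, size[2], size[1]))
}

#' Render one synthetic chamber frame
#'
#' Renders the organ at frame index `t` under the given period's
#' illumination statistics by an analytic point-in-boundary test at pixel
#' centers (no anti-aliasing), so the ground-truth pixel area is exactly
#' countable; the analytic area is reported alongside.  Night frames with
#' `jumpEmulation` on are rendered with the night camera's vertical shift
#' and bloom; the ground truth always records the true geometry.
#'
#' @param organ an [OrganModel-class].
#' @param illum an [IlluminationModel-class].
#' @param t frame index (0-based).
#' @param period `"day"` or `"night"`.
#' @param size image size `(H, W)` in pixels; default 576 x 768 (the
#'   chamber cameras' CCIR resolution).
#' @param seed integer seed for the noise (deterministic per frame).
#' @param dawnCount number of night-to-day transitions before `t` (drives
#'   the dawn-pulse mode; [simulateSequence] fills it in).
#' @param distractors optional list of static bright discs `c(x, y, r)`
#'   added to the scene (they are not part of the ground truth).
#' @return list with `image` (integer matrix) and `truth` (one-row data
#'   frame: `t`, `period`, `areaTrue`, `areaPx`, `cx`, `cy`, `a`, `b`,
#'   `angle`, `perimeterTrue`).
#' @export
renderFrame <- function(organ, illum, t, period = c("day", "night"),
                        size = c(576, 768), seed = 1, dawnCount = 0,
                        distractors = list()) {
  period <- match.arg(period)
  validObject(organ); validObject(illum)
  st <- organState(organ, t, size, dawnCount)
  checkInside(st, organ, illum, size, t)
  n <- organ@exponent
  trueMask <- organMask(st, n, size)
  night <- period == "night"
  if (night && illum@jumpEmulation) {
    seenMask <- organMask(st, n, size, grow = illum@nightBloomPx,
                          yShift = illum@nightShiftPx)
  } else {
    seenMask <- trueMask
  }
  bg <- if (night) illum@nightBg else illum@dayBg
  fg <- if (night) illum@nightFg else illum@dayFg
  img <- matrix(bg, size[1], size[2])
  for (d in distractors) {
    xs <- matrix(rep(0:(size[2] - 1), each = size[1]), size[1])
    ys <- matrix(rep(0:(size[1] - 1), size[2]), size[1])
    img[(xs - d[1])^2 + (ys - d[2])^2 <= d[3]^2] <- fg
  }
  img[seenMask] <- fg
  if (illum@noiseSd > 0) {
    set.seed((seed + 97 * t) %% .Machine$integer.max)
    img <- img + matrix(stats::rnorm(length(img), 0, illum@noiseSd),
                        size[1], size[2])
  }
  img <- clip255(img)
  ang <- st$angle %% 180
  truth <- data.frame(
    t = t, period = period,
    areaTrue = superellipseArea(st$a, st$b, n),
    areaPx = sum(trueMask), cx = st$cx, cy = st$cy,
    a = st$a, b = st$b, angle = ang,
    perimeterTrue = analyticPerimeter(st$a, st$b, n))
  list(image = img, truth = truth)
}

#' Simulate a full chamber time-lapse sequence
#'
#' One frame per scheduled capture instant of `plan`; night instants use
#' the night gray statistics (and camera artifacts, when emulated), day
#' instants the day statistics.  The whole sequence is verified to keep
#' the organ inside the frame before rendering, and is deterministic given
#' `seed`.
#'
#' @param organ an [OrganModel-class].
#' @param illum an [IlluminationModel-class].
#' @param plan an [ExperimentPlan-class].
#' @param seed integer seed.
#' @param size image size `(H, W)`; default 576 x 768.
#' @param distractors optional static bright discs, see [renderFrame].
#' @return a [ChamberSequence-class].
#' @export
simulateSequence <- function(organ, illum, plan, seed = 1,
                             size = c(576, 768), distractors = list()) {
  sched <- buildSchedule(plan)
  nf <- length(sched@instants)
  if (nf == 0) stop("plan yields no capture instants")
  dawnCounts <- cumsum(sched@transition == "T_nd") -
    as.integer(sched@transition[1] == "T_nd")  # the start-of-run dawn is not a pulse
  # verify bounds over the whole run before rendering anything (cheap:
  # analytic state only, no rasterization)
  for (i in seq_len(nf)) {
    st <- organState(organ, i - 1, size, dawnCounts[i])
    checkInside(st, organ, illum, size, i - 1)
  }
  frames <- vector("list", nf)
  truthRows <- vector("list", nf)
  for (i in seq_len(nf)) {
    r <- renderFrame(organ, illum, t = i - 1, period = sched@period[i],
                     size = size, seed = seed, dawnCount = dawnCounts[i],
                     distractors = distractors)
    frames[[i]] <- r$image
    tr <- r$truth
    tr$instant <- sched@instants[i]
    tr$transition <- sched@transition[i]
    truthRows[[i]] <- tr
  }
  new("ChamberSequence", frames = frames, schedule = sched,
      truth = do.call(rbind, truthRows), organ = organ, illum = illum,
      seed = seed)
}

setMethod("show", "ChamberSequence", function(object) {
  cat(sprintf(
    "ChamberSequence: %d frames (%d day, %d night), %dx%d px, seed %g\n",
    length(object@frames), sum(object@schedule@period == "day"),
    sum(object@schedule@period == "night"),
    ncol(object@frames[[1]]), nrow(object@frames[[1]]), object@seed))
})

setMethod("length", "ChamberSequence", function(x) length(x@frames))
#' @rdname groundTruth
setMethod("groundTruth", "ChamberSequence", function(x) x@truth)
#' @rdname chamberFrames
setMethod("chamberFrames", "ChamberSequence", function(x) x@frames)
#' @rdname scheduleTable
setMethod("scheduleTable", "ChamberSequence", function(x) scheduleTable(x@schedule))

#' Write a simulated sequence to disk
#'
#' Frames as image files named `frame_<index>_<period>.<ext>` (index =
#' 0-based frame number, zero-padded), the ground truth as
#' `ground_truth.csv` and the schedule as `schedule.csv`.
#'
#' @param seq a [ChamberSequence-class].
#' @param dir output directory (created if missing).
#' @param format `"png"` (default), `"tiff"`, `"jpg"` or `"bmp"`.
#' @return character vector of frame file paths, invisibly.
#' @export
writeFrames <- function(seq, dir, format = c("png", "tiff", "jpg", "bmp")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- length(seq@frames)
  paths <- character(n)
  for (i in seq_len(n)) {
    fn <- sprintf("frame_%06d_%s.%s", i - 1, seq@schedule@period[i], format)
    paths[i] <- file.path(dir, fn)
    writeFrame(seq@frames[[i]], paths[i])
  }
  truth <- seq@truth
  truth$instant <- format(truth$instant, "%Y-%m-%d %H:%M:%S")
  utils::write.csv(truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  writeScheduleCsv(seq@schedule, file.path(dir, "schedule.csv"))
  invisible(paths)
}
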