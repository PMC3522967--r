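#' @include AllClasses.R AllGenerics.R segmentation.R
NULL

#' Create a calibration target description
#'
#' Default geometry: 100 circles in ten columns and ten rows, radius 5 mm,
#' with a 10 mm gap between neighbouring circles (20 mm center-to-center
#' pitch).
#'
#' @param rows,cols grid dimensions.
#' @param circleRadiusMm circle radius, mm.
#' @param pitchMm center-to-center separation, mm (> circle diameter).
#' @return a [CalibrationTarget-class].
#' @export
calibrationTarget <- function(rows = 10, cols = 10, circleRadiusMm = 5,
                              pitchMm = 20) {
  new("CalibrationTarget", rows = rows, cols = cols,
      circleRadiusMm = circleRadiusMm, pitchMm = pitchMm)
}

setMethod("show", "CalibrationTarget", function(object) {
  cat(sprintf(
    "CalibrationTarget: %g x %g circles, radius %g mm, pitch %g mm\n",
    object@rows, object@cols, object@circleRadiusMm, object@pitchMm))
})

#' Render a synthetic calibration-grid image
#'
#' Dark circles on a light background at a known mm-per-pixel scale, used
#' to exercise and validate the calibration chain.  Circles are rasterized
#' by the pixel-center point-in-circle test.
#'
#' @param target a [CalibrationTarget-class].
#' @param scaleMmPerPx rendering scale, mm per pixel (isotropic).
#' @param marginPx image margin around the outer circles, px.
#' @param fg,bg circle / background gray levels.
#' @return list with `image` (integer matrix) and `centers` (data frame of
#'   true centers `x`, `y` in px, row-major order).
#' @export
renderCalibrationGrid <- function(target, scaleMmPerPx = 0.25,
                                  marginPx = 20, fg = 40, bg = 215) {
  pitchPx <- target@pitchMm / scaleMmPerPx
  rPx <- target@circleRadiusMm / scaleMmPerPx
  cxs <- marginPx + rPx + (seq_len(target@cols) - 1) * pitchPx
  cys <- marginPx + rPx + (seq_len(target@rows) - 1) * pitchPx
  W <- ceiling(max(cxs) + rPx + marginPx) + 1
  H <- ceiling(max(cys) + rPx + marginPx) + 1
  img <- matrix(bg, H, W)
  xs <- matrix(rep(0:(W - 1), each = H), H)
  ys <- matrix(rep(0:(H - 1), W), H)
  centers <- expand.grid(x = cxs, y = cys)[, c("x", "y")]
  centers <- centers[order(centers$y, centers$x), ]
  for (i in seq_len(nrow(centers))) {
    m <- (xs - centers$x[i])^2 + (ys - centers$y[i])^2 <= rPx^2
    img[m] <- fg
  }
  rownames(centers) <- NULL
  list(image = img, centers = centers)
}

#' Detect the circle centers of a calibration grid image
#'
#' Otsu-thresholds the image with automatic polarity (the circles are the
#' minority class), extracts 8-connected blobs, keeps circle-like blobs
#' (compactness below 1.3, area above a noise floor), and returns their
#' intensity-weighted centroids ordered row-major (rows found by
#' clustering center y-coordinates, sorted by x within rows).
#'
#' @param img integer matrix 0-255.
#' @param target a [CalibrationTarget-class] (for the expected count and
#'   row structure).
#' @return data frame of centers `x`, `y` (px, 0-based), row-major, with
#'   a `radiusPx` column (circle-equivalent radius from the blob area).
#' @export
detectGridCircles <- function(img, target) {
  expected <- target@rows * target@cols
  lvl <- tryCatch(thresholdOtsu(img), error = function(e) NULL)
  if (is.null(lvl))
    stop("calibration image detection failed: 0 circles found (expected ",
         expected, "); image has no contrast")
  fgBright <- img > lvl
  # circles are the minority class
  bin <- if (sum(fgBright) <= length(img) / 2) fgBright else !fgBright
  blobs <- extractBlobs(bin)
  blobs <- filterBlobs(blobs, list(areaMin = 9, compactnessMax = 1.3))
  if (nrow(blobs) != expected)
    stop(sprintf(
      "detected %d circle candidate(s), expected %d; candidate areas: %s",
      nrow(blobs), expected,
      paste(utils::head(round(blobs$area), 20), collapse = ", ")))
  # intensity-weighted centroids (weight = darkness for dark circles)
  H <- nrow(img)
  wimg <- if (sum(fgBright) <= length(img) / 2) img else 255 - img
  cx <- numeric(expected); cy <- numeric(expected)
  for (i in seq_len(expected)) {
    px <- blobs$pixels[[i]]
    y <- (px - 1) %% H          # 0-based
    x <- (px - 1) %/% H
    w <- wimg[px]
    cx[i] <- sum(w * x) / sum(w)
    cy[i] <- sum(w * y) / sum(w)
  }
  r <- sqrt(blobs$npix / pi)
  # row-major ordering: cluster y into rows, then sort by x
  rowPitch <- (max(cy) - min(cy)) / (target@rows - 1)
  rowIdx <- round((cy - min(cy)) / rowPitch)
  if (length(unique(rowIdx)) != target@rows ||
      any(table(rowIdx) != target@cols))
    stop("detected centers do not form the expected row structure")
  o <- order(rowIdx, cx)
  data.frame(x = cx[o], y = cy[o], radiusPx = r[o])
}

#' Fit the pixel-to-mm scale of one calibration plane
#'
#' `scaleX` = pitch (mm) / mean horizontal center spacing (px) and
#' `scaleY` analogously from the vertical spacing.  The residual is the
#' RMS deviation of the detected centers from the ideal grid after a
#' least-squares similarity (rotation + translation + scale) fit, in mm.
#'
#' @param centers data frame of centers `x`, `y` (px), row-major, as
#'   returned by [detectGridCircles].
#' @param target a [CalibrationTarget-class].
#' @param distanceMm distance of the calibrated plane from the camera.
#' @return a [PlaneCalibration-class].
#' @export
fitPlaneScale <- function(centers, target, distanceMm = NA_real_) {
  R <- target@rows; C <- target@cols
  if (nrow(centers) != R * C)
    stop("need rows x cols centers in row-major order")
  X <- matrix(centers$x, nrow = C)   # column r = row r of the grid
  Y <- matrix(centers$y, nrow = C)
  meanDx <- mean(apply(X, 2, function(v) mean(diff(v))))   # within grid rows
  meanDy <- mean(apply(Y, 1, function(v) mean(diff(v))))   # across grid rows
  if (meanDx <= 0 || meanDy <= 0)
    stop("degenerate center layout: non-positive mean spacing")
  scaleX <- target@pitchMm / meanDx
  scaleY <- target@pitchMm / meanDy
  # similarity fit px -> mm against the ideal grid
  ideal <- expand.grid(x = (seq_len(C) - 1) * target@pitchMm,
                       y = (seq_len(R) - 1) * target@pitchMm)
  ideal <- ideal[order(ideal$y, ideal$x), ]
  P <- cbind(centers$x, centers$y)
  Q <- cbind(ideal$x, ideal$y)
  Pc <- scale(P, scale = FALSE); Qc <- scale(Q, scale = FALSE)
  if (sum(Pc^2) < 1e-12) stop("degenerate (collinear or coincident) centers")
  S <- crossprod(Pc, Qc)
  sv <- svd(S)
  Rm <- sv$v %*% t(sv$u)
  if (det(Rm) < 0) { sv$v[, 2] <- -sv$v[, 2]; Rm <- sv$v %*% t(sv$u) }
  s <- sum(diag(t(Rm) %*% S)) / sum(Pc^2)
  resid <- sqrt(mean(rowSums((Qc - s * Pc %*% t(Rm))^2)))
  new("PlaneCalibration", distanceMm = distanceMm, scaleX = scaleX,
      scaleY = scaleY, residualMm = resid)
}

setMethod("show", "PlaneCalibration", function(object) {
  cat(sprintf(
    "PlaneCalibration @ %g mm: scale (%.5f, %.5f) mm/px, residual %.4f mm\n",
    object@distanceMm, object@scaleX, object@scaleY, object@residualMm))
})

#' Assemble a multi-plane calibration model
#'
#' @param planes list of [PlaneCalibration-class] objects (any order;
#'   sorted by distance, which must be unique).
#' @return a [CalibrationModel-class].
#' @export
calibrationModel <- function(planes) {
  df <- do.call(rbind, lapply(planes, function(p)
    data.frame(distanceMm = p@distanceMm, scaleX = p@scaleX,
               scaleY = p@scaleY, residualMm = p@residualMm)))
  if (anyDuplicated(df$distanceMm)) stop("duplicate plane distances")
  df <- df[order(df$distanceMm), ]
  rownames(df) <- NULL
  new("CalibrationModel", planes = df)
}

#' @rdname calibrationPlanes
setMethod("calibrationPlanes", "CalibrationModel", function(x) x@planes)

setMethod("show", "CalibrationModel", function(object) {
  p <- object@planes
  cat(sprintf(
    "CalibrationModel: %d plane(s) spanning %g-%g mm\n",
    nrow(p), min(p$distanceMm), max(p$distanceMm)))
})

#' @rdname scaleAtDistance
setMethod("scaleAtDistance", "CalibrationModel", function(model, distanceMm) {
  p <- model@planes
  if (distanceMm < min(p$distanceMm) || distanceMm > max(p$distanceMm))
    stop(sprintf(
      "distance %g mm outside the calibrated range [%g, %g] mm (no extrapolation)",
      distanceMm, min(p$distanceMm), max(p$distanceMm)))
  c(scaleX = stats::approx(p$distanceMm, p$scaleX, distanceMm)$y,
    scaleY = stats::approx(p$distanceMm, p$scaleY, distanceMm)$y)
})

#' Persist / load a calibration model as JSON
#'
#' @param model a [CalibrationModel-class].
#' @param path JSON file path.
#' @return `path` invisibly (write) / a [CalibrationModel-class] (read).
#' @export
writeCalibrationJson <- function(model, path) {
  jsonlite::write_json(model@planes, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeCalibrationJson
#' @export
readCalibrationJson <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("CalibrationModel", planes = as.data.frame(df))
}
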