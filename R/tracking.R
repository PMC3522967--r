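#' @include AllClasses.R AllGenerics.R segmentation.R
NULL

# segmentFrame that treats an untresholdable (constant) region as empty
# instead of an error, so ROI recovery can proceed
safeSegment <- function(img, config, roi = NULL) {
  tryCatch(segmentFrame(img, config, roi = roi),
           error = function(e) {
             if (grepl("distinct gray levels", conditionMessage(e)))
               list(binary = NULL, level = NA,
                    blobs = extractBlobs(matrix(FALSE, 1, 1)))
             else stop(e)
           })
}

expandClamp <- function(rc, mgx, mgy, bounds) {
  c(max(0, rc[1] - mgx), max(0, rc[2] - mgy),
    min(bounds[2] - 1, rc[3] + mgx), min(bounds[1] - 1, rc[4] + mgy))
}

# blob identity rule: largest area wins; when several candidates are within
# 10% of the largest area, the one whose centroid is nearest `ref` wins.
selectBlob <- function(blobs, ref = NULL) {
  if (!nrow(blobs)) return(NULL)
  amax <- max(blobs$area)
  cand <- which(blobs$area >= 0.9 * amax)
  if (length(cand) > 1 && !is.null(ref)) {
    d <- sqrt((blobs$cx[cand] - ref[1])^2 + (blobs$cy[cand] - ref[2])^2)
    cand <- cand[which.min(d)]
  } else {
    cand <- cand[which.max(blobs$area[cand])]
  }
  blobs[cand, , drop = FALSE]
}

#' Initialize the adaptive ROI from a user-selected rectangle
#'
#' Segments the first frame inside the user rectangle; the largest blob is
#' taken as the organ.  The initial ROI is the blob's circumscribed
#' rectangle expanded by the margins `(mgx, mgy)` — the maximum expected
#' growth plus displacement per capture interval along each axis — and
#' clamped to the image bounds.
#'
#' @param img first frame, integer matrix 0-255.
#' @param userRect rectangle `(xmin, ymin, xmax, ymax)`, 0-based inclusive,
#'   within the image.
#' @param config a [PipelineConfig-class].
#' @param mgx,mgy growth margins in pixels (>= 0).
#' @return an [AROIState-class].
#' @export
initRoi <- function(img, userRect, config, mgx = 10, mgy = 10) {
  seg <- safeSegment(img, config, roi = userRect)
  blob <- selectBlob(seg$blobs)
  if (is.null(blob)) stop("no blob found in the initial ROI")
  rc <- c(blob$xmin, blob$ymin, blob$xmax, blob$ymax)
  new("AROIState", roi = expandClamp(rc, mgx, mgy, dim(img)), rc = rc,
      mgx = mgx, mgy = mgy, bounds = dim(img),
      lastCentroid = c(blob$cx, blob$cy), lastArea = blob$area)
}

#' @rdname currentRoi
setMethod("currentRoi", "AROIState", function(x) x@roi)

setMethod("show", "AROIState", function(object) {
  cat(sprintf(
    "AROIState: ROI (%g, %g)-(%g, %g), RC (%g, %g)-(%g, %g), margins (%g, %g)\n",
    object@roi[1], object@roi[2], object@roi[3], object@roi[4],
    object@rc[1], object@rc[2], object@rc[3], object@rc[4],
    object@mgx, object@mgy))
})

#' Advance the adaptive ROI by one frame
#'
#' Segments the new frame inside the current ROI, picks the tracked blob
#' (largest area; nearest previous centroid among blobs within 10% of the
#' largest), and recomputes the ROI as the blob rectangle expanded
#' symmetrically by the margins and clamped to the image.  If the ROI
#' turns up empty the full frame is re-segmented once and the blob nearest
#' the last known centroid is taken (the organ may have left a clamped
#' ROI); if that also fails an error is raised.
#'
#' @param state an [AROIState-class].
#' @param img the new frame.
#' @param config a [PipelineConfig-class].
#' @return list with `state` (advanced [AROIState-class]) and `blob` (the
#'   accepted blob's feature row).
#' @export
updateAroi <- function(state, img, config) {
  seg <- safeSegment(img, config, roi = round(state@roi))
  blob <- selectBlob(seg$blobs, ref = state@lastCentroid)
  if (is.null(blob)) {
    seg <- safeSegment(img, config)   # recovery: one full-frame pass
    b <- seg$blobs
    if (nrow(b)) {
      d <- sqrt((b$cx - state@lastCentroid[1])^2 +
                (b$cy - state@lastCentroid[2])^2)
      blob <- b[which.min(d), , drop = FALSE]
    }
  }
  if (is.null(blob)) stop("organ lost: no blob in ROI nor in the full frame")
  rc <- c(blob$xmin, blob$ymin, blob$xmax, blob$ymax)
  st <- new("AROIState",
            roi = expandClamp(rc, state@mgx, state@mgy, state@bounds),
            rc = rc, mgx = state@mgx, mgy = state@mgy,
            bounds = state@bounds, lastCentroid = c(blob$cx, blob$cy),
            lastArea = blob$area)
  list(state = st, blob = blob)
}

#' Track one organ across a frame sequence
#'
#' Runs the adaptive-ROI loop over all frames: per-frame segmentation
#' restricted to the ROI, blob identity by the largest-area /
#' nearest-centroid rule, ROI recomputation with the configured margins.
#' Frames where recovery fails are flagged missing (features `NA`), never
#' interpolated, and tracking continues from the last good state.
#'
#' @param frames list of integer matrices, or a [ChamberSequence-class].
#' @param userRect initial user-selected rectangle
#'   `(xmin, ymin, xmax, ymax)`.
#' @param config a [PipelineConfig-class].
#' @param mgx,mgy growth margins, px.
#' @param schedule optional [CaptureSchedule-class] aligning frames to
#'   instants/periods (taken from the sequence when `frames` is a
#'   [ChamberSequence-class]).
#' @return an [OrganTrack-class].
#' @export
trackSequence <- function(frames, userRect, config, mgx = 10, mgy = 10,
                          schedule = NULL) {
  if (is(frames, "ChamberSequence")) {
    if (is.null(schedule)) schedule <- frames@schedule
    frames <- frames@frames
  }
  n <- length(frames)
  if (n < 1) stop("need at least one frame")
  st <- initRoi(frames[[1]], userRect, config, mgx, mgy)
  cols <- c("area", "perimeter", "length", "angle", "cx", "cy", "compactness")
  feat <- as.data.frame(matrix(NA_real_, n, length(cols)))
  names(feat) <- cols
  rois <- matrix(NA_real_, n, 4,
                 dimnames = list(NULL, c("xmin", "ymin", "xmax", "ymax")))
  missing <- rep(FALSE, n)
  # frame 1: features of the blob initRoi selected (re-segment inside its RC margin ROI)
  fill <- function(i, blob) {
    feat[i, ] <<- unlist(blob[1, cols])
  }
  seg1 <- segmentFrame(frames[[1]], config, roi = round(userRect))
  b1 <- selectBlob(seg1$blobs)
  fill(1, b1)
  rois[1, ] <- st@roi
  for (i in seq_len(n)[-1]) {
    res <- tryCatch(updateAroi(st, frames[[i]], config), error = function(e) NULL)
    if (is.null(res)) {
      missing[i] <- TRUE
      rois[i, ] <- st@roi
      next
    }
    st <- res$state
    fill(i, res$blob)
    rois[i, ] <- st@roi
  }
  feat$missing <- missing
  feat$frame <- seq_len(n) - 1L
  if (!is.null(schedule) && length(schedule@instants) == n) {
    feat$instant <- schedule@instants
    feat$period <- schedule@period
    feat$transition <- schedule@transition
  } else {
    feat$instant <- as.POSIXct(NA)
    feat$period <- NA_character_
    feat$transition <- NA_character_
  }
  ord <- c("frame", "instant", "period", "transition", cols, "missing")
  new("OrganTrack", features = feat[, ord], rois = rois, mgx = mgx,
      mgy = mgy, config = config)
}

#' @rdname trackFeatures
setMethod("trackFeatures", "OrganTrack", function(x) x@features)

#' ROI rectangles of a track
#' @param track an [OrganTrack-class].
#' @return matrix (frames x 4) of `(xmin, ymin, xmax, ymax)` rectangles.
#' @export
trackRois <- function(track) track@rois

setMethod("length", "OrganTrack", function(x) nrow(x@features))

setMethod("show", "OrganTrack", function(object) {
  f <- object@features
  cat(sprintf(
    "OrganTrack: %d frame(s), %d missing; margins (%g, %g)\n",
    nrow(f), sum(f$missing), object@mgx, object@mgy))
})

#' Motion-vector series of a track
#'
#' [motionVector] applied to the track's centroid series.  Missing frames
#' give `NA`.
#'
#' @param track an [OrganTrack-class].
#' @return numeric MV series (px), first value 0.
#' @export
trackMotionVector <- function(track) {
  f <- track@features
  motionVector(f$cx, f$cy)
}

#' Export a track as CSV
#' @param track an [OrganTrack-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTrackCsv <- function(track, path) {
  df <- cbind(track@features, as.data.frame(track@rois))
  df$instant <- format(df$instant, "%Y-%m-%d %H:%M:%S")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
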