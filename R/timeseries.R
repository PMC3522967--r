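#' @include AllClasses.R AllGenerics.R tracking.R
NULL

#' Correct day/night illumination-transition discontinuities
#'
#' Pixel-counting variables (area, length, centroid coordinates,
#' perimeter) jump abruptly where the capture switches between the day and
#' night imaging set-ups.  For each period transition, taken in time
#' order, the correction offsets every sample from the transition onward
#' so that the step across the transition equals the mean successive
#' difference of the period that just ended: with `K1` the observed jump
#' at a night-to-day transition and `K2` the mean within-night successive
#' difference, the applied offset is `-K1 + K2` (analogously `-K3 + K4`
#' for day-to-night); offsets accumulate across successive transitions.
#' Within-period successive differences are preserved exactly; only the
#' inter-period offsets change.  A transition with no preceding period
#' (the schedule's first instant) is skipped.
#'
#' @param values numeric series, one value per capture instant.
#' @param periods period label per sample (`"day"`/`"night"`), or a
#'   [CaptureSchedule-class] of the same length.
#' @return numeric corrected series, same length.
#' @examples
#' v <- c(0, 1, 2, 3, 10, 11, 12, 13)
#' p <- rep(c("night", "day"), each = 4)
#' correctTransitions(v, p)  # 0 1 2 3 4 5 6 7
#' @export
correctTransitions <- function(values, periods) {
  if (is(periods, "CaptureSchedule")) periods <- periods@period
  n <- length(values)
  if (length(periods) != n)
    stop("values and periods must have the same length")
  if (n < 2) return(values)
  trans <- which(periods[-1] != periods[-n]) + 1L
  corrected <- values
  offset <- 0
  runStart <- 1L
  for (m in trans) {
    run <- runStart:(m - 1L)
    if (length(run) < 2)
      stop(sprintf("period '%s' ending at sample %d has fewer than 2 samples; cannot estimate its mean step",
                   periods[m - 1L], m - 1L))
    K <- mean(diff(values[run]))          # mean step of the period just ended
    jump <- values[m] - values[m - 1L]    # observed step across the transition
    offset <- offset + (-jump + K)
    corrected[m:n] <- values[m:n] + offset
    runStart <- m
  }
  corrected
}

#' Accumulated growth of a (corrected) series
#'
#' Sum of the positive increments only, anchored at 0:
#' `acc_j = sum over k < j of max(0, V_{k+1} - V_k)`.  Measurement dips
#' (an organ turning toward the camera) therefore never reduce the
#' accumulated total.  The output is monotone non-decreasing and starts
#' at 0; for a monotone input it equals `V - V[1]`.
#'
#' @param values numeric series (after [correctTransitions]).
#' @return accumulated series, same length.
#' @examples
#' accumulateGrowth(c(5, 7, 6, 9))  # 0 2 2 5
#' @export
accumulateGrowth <- function(values) {
  if (!length(values)) return(numeric(0))
  c(0, cumsum(pmax(diff(values), 0)))
}

#' Binary diel growth pattern from accumulated series
#'
#' Splits the accumulated area and length series into consecutive
#' intervals of `samplesPerInterval` capture steps (e.g. 8 h intervals =
#' 3 intervals/day) and flags each interval 1 when the accumulated series
#' increases over it by more than epsilon, a configurable fraction
#' (default 1%) of the series' total range.  Invariant to adding a
#' constant to a whole series.  Intervals where length grows but area
#' does not reveal the decoupling of proximo-distal and lateral growth.
#'
#' @param accArea,accLength accumulated series (equal length, covering an
#'   integer number of intervals: `length = k * samplesPerInterval`; a
#'   trailing partial interval is ignored).
#' @param samplesPerInterval capture samples per interval (>= 2; e.g. a
#'   7-day run at 6 images/hour split into 8-h intervals has 48 samples
#'   per interval and 21 intervals).
#' @param epsFrac epsilon as a fraction of each series' total range.
#' @return a [GrowthPattern-class].
#' @export
binarizeGrowth <- function(accArea, accLength, samplesPerInterval,
                           epsFrac = 0.01) {
  n <- length(accArea)
  if (length(accLength) != n) stop("series lengths differ")
  m <- as.integer(samplesPerInterval)
  if (m < 2) stop("samplesPerInterval must be >= 2")
  if (n < m) stop("series shorter than one interval")
  k <- n %/% m
  flag1 <- function(v) {
    eps <- epsFrac * diff(range(v))
    starts <- (seq_len(k) - 1L) * m + 1L
    as.integer(v[starts + m - 1L] - v[starts] > eps)
  }
  flags <- data.frame(interval = seq_len(k), area = flag1(accArea),
                      length = flag1(accLength))
  new("GrowthPattern", flags = flags, samplesPerInterval = m,
      epsilon = c(area = epsFrac * diff(range(accArea)),
                  length = epsFrac * diff(range(accLength))))
}

#' @rdname patternFlags
setMethod("patternFlags", "GrowthPattern", function(x) x@flags)

setMethod("show", "GrowthPattern", function(object) {
  f <- object@flags
  cat(sprintf("GrowthPattern: %d interval(s) of %d sample(s)\n",
              nrow(f), object@samplesPerInterval))
  cat("  area:  ", paste(f$area, collapse = " "), "\n")
  cat("  length:", paste(f$length, collapse = " "), "\n")
})

#' Write a growth-pattern matrix as CSV
#' @param pattern a [GrowthPattern-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePatternCsv <- function(pattern, path) {
  utils::write.csv(pattern@flags, path, row.names = FALSE)
  invisible(path)
}

#' Rank tracked organs for rhythm analysis
#'
#' Scores each organ on (a) visibility, the fraction of frames with a
#' valid measurement; (b) occlusion, the fraction of frames in which its
#' bounding box overlaps another organ's by more than `overlapFrac` of its
#' own box area (organs partially or completely overshadowed by another
#' are discarded); and (c) activity, the variance of its motion vector.
#' Organs failing the visibility or occlusion thresholds are discarded;
#' survivors are ranked by activity, descending — for nutation studies the
#' organs showing the most movement are the ones to keep.
#'
#' @param tracks list of [OrganTrack-class] objects.
#' @param minVisibility minimum valid-frame fraction (default 0.8).
#' @param overlapFrac bounding-box overlap fraction that counts as
#'   occluded in a frame (default 0.5).
#' @param maxOccludedFrames maximum tolerated fraction of occluded frames
#'   (default 0.5).
#' @return data frame, one row per organ, ordered best first: `organ`,
#'   `visibility`, `occlusion`, `activity`, `retained`, `rank` (`NA` for
#'   discarded organs).
#' @export
rankOrgans <- function(tracks, minVisibility = 0.8, overlapFrac = 0.5,
                       maxOccludedFrames = 0.5) {
  if (!length(tracks)) stop("empty track list")
  k <- length(tracks)
  feats <- lapply(tracks, function(tr) tr@features)
  vis <- vapply(feats, function(f) mean(!f$missing), 0)
  boxes <- lapply(tracks, function(tr) {
    f <- tr@features
    # per-frame blob bounding boxes reconstructed from centroid/extent are
    # not stored; use the ROI minus margins (= the blob's RC)
    r <- tr@rois
    cbind(r[, 1] + tr@mgx, r[, 2] + tr@mgy, r[, 3] - tr@mgx, r[, 4] - tr@mgy)
  })
  occl <- numeric(k)
  if (k > 1) {
    nf <- min(vapply(boxes, nrow, 0L))
    for (i in seq_len(k)) {
      hit <- rep(FALSE, nf)
      bi <- boxes[[i]]
      areaI <- pmax(0, bi[, 3] - bi[, 1] + 1) * pmax(0, bi[, 4] - bi[, 2] + 1)
      for (j in seq_len(k)[-i]) {
        bj <- boxes[[j]]
        ix <- pmax(0, pmin(bi[1:nf, 3], bj[1:nf, 3]) - pmax(bi[1:nf, 1], bj[1:nf, 1]) + 1)
        iy <- pmax(0, pmin(bi[1:nf, 4], bj[1:nf, 4]) - pmax(bi[1:nf, 2], bj[1:nf, 2]) + 1)
        hit <- hit | (ix * iy / areaI[1:nf] > overlapFrac)
      }
      occl[i] <- mean(hit)
    }
  }
  act <- vapply(tracks, function(tr) {
    mv <- trackMotionVector(tr)
    stats::var(mv[!is.na(mv)])
  }, 0)
  retained <- vis >= minVisibility & occl <= maxOccludedFrames
  out <- data.frame(organ = seq_len(k), visibility = vis, occlusion = occl,
                    activity = act, retained = retained,
                    rank = NA_integer_)
  out$rank[retained] <- rank(-act[retained], ties.method = "first")
  out[order(!out$retained, out$rank), ]
}
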