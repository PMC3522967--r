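#' @include AllClasses.R
NULL

# ---- internal geometry helpers ----------------------------------------------

# Moore-neighbor contour tracing of the outer boundary of a connected mask.
# mask: logical matrix [y, x]. Returns the chain code (0..7, clockwise on
# screen starting at W) of the closed outer contour, or integer(0) for a
# single-pixel mask. Termination: stop when the post-first-step state
# (position, direction) repeats.
traceContour <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  o <- order(idx[, 1], idx[, 2])
  sy <- idx[o[1], 1]; sx <- idx[o[1], 2]
  dy <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)   # W NW N NE E SE S SW
  dx <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  cy <- sy; cx <- sx; dir <- 4L                # as if entered moving East
  steps <- integer(0)
  y0 <- NA_integer_; x0 <- NA_integer_; d0 <- NA_integer_
  maxSteps <- 4L * nrow(idx) + 8L
  repeat {
    hit <- -1L
    for (k in 1:8) {
      d <- (dir + 4L + k) %% 8L
      y <- cy + dy[d + 1L]; x <- cx + dx[d + 1L]
      if (y >= 1L && y <= H && x >= 1L && x <= W && mask[y, x]) {
        hit <- d; cy <- y; cx <- x
        break
      }
    }
    if (hit < 0L) return(integer(0))           # isolated pixel
    if (is.na(d0)) { y0 <- cy; x0 <- cx; d0 <- hit }
    else if (cy == y0 && cx == x0 && hit == d0) break
    steps <- c(steps, hit)
    dir <- hit
    if (length(steps) > maxSteps) break        # safety; cannot trigger on valid masks
  }
  steps
}

# Perimeter from the traced chain code with Kulpa weights (0.948 per axial
# step, 1.340 per diagonal step), a low-bias estimator for smooth digitized
# outlines (disc bias about -1%). Single-pixel masks get the
# circle-equivalent perimeter 2*sqrt(pi).
maskPerimeter <- function(mask) {
  steps <- traceContour(mask)
  if (!length(steps)) return(2 * sqrt(pi))
  axial <- sum(steps %% 2L == 0L)
  diago <- sum(steps %% 2L == 1L)
  0.948 * axial + 1.340 * diago
}

# ---- exported feature operations --------------------------------------------

#' Shape features of a binary mask
#'
#' Computes the primitive shape descriptors of one connected foreground
#' region: area (pixel count), perimeter (Moore contour with Kulpa chain
#' weights), center of gravity, principal-axis angle and length, bounding
#' rectangle, and compactness.
#'
#' Conventions: pixel coordinates are 0-based at pixel centers, x rightward
#' and y downward; the angle is measured counter-clockwise from the
#' horizontal axis with y taken upward, reported in `[0, 180)` degrees.
#' When the second moments are isotropic the angle is degenerate and
#' reported as 0 with `degenerate = TRUE`.  Length is the full extent of
#' the mask along the principal axis (rotated-bounding-box length,
#' pixel-center extent + 1).
#'
#' An isotropic metric scale (mm/pixel) may be supplied: areas scale by
#' `scale^2`, all linear measures by `scale`.
#'
#' @param mask logical (or 0/1) matrix, `mask[y, x]`; must be nonempty.
#' @param scale optional isotropic scale in mm/pixel (default 1 = pixels).
#' @param offset `(x, y)` offset added to reported coordinates (used when
#'   the mask is a crop of a larger image).
#' @return a list with `area`, `perimeter`, `length`, `angle`, `cx`, `cy`,
#'   `compactness`, `bbox` (`xmin, ymin, xmax, ymax`, 0-based inclusive),
#'   `npix`, `degenerate`.
#' @examples
#' m <- matrix(FALSE, 12, 12); m[2:11, 2:11] <- TRUE
#' computeShape(m)$area   # 100
#' @export
computeShape <- function(mask, scale = 1, offset = c(0, 0)) {
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  idx <- which(mask, arr.ind = TRUE)
  xs <- idx[, 2] - 1 + offset[1]
  ys <- idx[, 1] - 1 + offset[2]
  npix <- nrow(idx)
  cx <- mean(xs); cy <- mean(ys)
  dxv <- xs - cx; dyu <- -(ys - cy)          # y upward for angle math
  mu20 <- mean(dxv^2); mu02 <- mean(dyu^2); mu11 <- mean(dxv * dyu)
  degen <- abs(mu20 - mu02) < 1e-9 && abs(mu11) < 1e-9
  ang <- if (degen) 0 else {
    a <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
    if (a < 0) a <- a + 180
    if (a >= 180) a <- a - 180
    a
  }
  th <- ang * pi / 180
  proj <- dxv * cos(th) + dyu * sin(th)
  len <- diff(range(proj)) + 1
  p <- maskPerimeter(mask)
  A <- npix
  bbox <- c(min(xs), min(ys), max(xs), max(ys))
  list(area = A * scale^2, perimeter = p * scale, length = len * scale,
       angle = ang, cx = cx * scale, cy = cy * scale,
       compactness = compactness(A * scale^2, p * scale),
       bbox = bbox, npix = npix, degenerate = degen)
}

#' Compactness of a shape
#'
#' `C = p^2 / (4 * pi * A)`.  Equals 1 for a perfect circle
#' (`p = 2*pi*r`, `A = pi*r^2`) and grows for elongated or irregular
#' outlines; digitized discs land near 1 (within a few percent, from the
#' perimeter estimator's small bias).
#'
#' @param A area (> 0).
#' @param p perimeter (> 0), same length unit.
#' @return dimensionless compactness.
#' @examples
#' compactness(pi * 10^2, 2 * pi * 10)  # 1
#' @export
compactness <- function(A, p) {
  if (any(A <= 0) || any(p <= 0)) stop("area and perimeter must be > 0")
  p^2 / (4 * pi * A)
}

#' Motion vector of a centroid track
#'
#' Displacement modulus of each centroid from the organ's origin, the
#' centroid position in the first frame:
#' `MV_i = sqrt((cx_i - cx_o)^2 + (cy_i - cy_o)^2)`.  The first value is 0
#' by construction.  Positive and negative swings of the underlying
#' position over short spans show up as high MV activity; a flat MV means
#' low movement.
#'
#' @param cx,cy centroid coordinate series (equal length, >= 1). `cx` may
#'   also be a 2-column matrix/data frame of `(cx, cy)`.
#' @return numeric MV series, same length.
#' @examples
#' motionVector(c(0, 3), c(0, 4))  # 0 5
#' @export
motionVector <- function(cx, cy = NULL) {
  if (is.null(cy)) {
    m <- as.matrix(cx)
    stopifnot(ncol(m) == 2)
    cx <- m[, 1]; cy <- m[, 2]
  }
  if (length(cx) == 0) stop("empty centroid track")
  if (length(cx) != length(cy)) stop("cx and cy lengths differ")
  sqrt((cx - cx[1])^2 + (cy - cy[1])^2)
}

#' Growth velocity of a measured series
#'
#' Forward difference of a measured length (or area) series divided by the
#' capture interval: `v_j = (l_{j+1} - l_j) / dt`, `j = 1..N-1`.  Values
#' may be negative: an organ turning toward the camera shrinks in apparent
#' size even while growing.
#'
#' @param l measured series (length >= 2).
#' @param dt capture interval (> 0), in the time unit the velocity should
#'   be expressed per.
#' @return numeric vector of `N - 1` velocities.
#' @examples
#' growthVelocity(c(10, 13), dt = 1)  # 3
#' @export
growthVelocity <- function(l, dt) {
  if (length(l) < 2) stop("need at least 2 samples")
  if (dt <= 0) stop("dt must be > 0")
  diff(l) / dt
}
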