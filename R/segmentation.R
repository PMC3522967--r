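#' @include AllClasses.R features.R
NULL

# images are integer matrices [y, x] in 0..255; EBImage stores [x, y] in [0,1]
toEBI <- function(img) EBImage::Image(t(img) / 255)
fromEBI <- function(e) {
  m <- t(as.matrix(EBImage::imageData(e))) * 255
  clip255(m)
}
clip255 <- function(m) {
  m[m < 0] <- 0; m[m > 255] <- 255
  m <- round(m)
  storage.mode(m) <- "integer"
  m
}

#' Create a segmentation pipeline configuration
#'
#' @param preprocessing ordered list (at most 4) of operations built with
#'   [preprocessOp].
#' @param edgeDetector `"none"` (default), `"roberts"` or `"sobel"`; when
#'   set, the gradient-magnitude image replaces the input before
#'   thresholding (useful for kinky organ outlines).  Segmentation always
#'   proceeds via thresholding, never from the edge map directly.
#' @param thresholdMethod `"otsu"` (default), `"kapur"`, `"kittler"` or
#'   `"fixed"`.
#' @param fixedLevel threshold level for `"fixed"`.
#' @param invert invert gray levels first (organ darker than background).
#' @param blobFilters named list of bounds, see [filterBlobs].
#' @return a [PipelineConfig-class].
#' @examples
#' pipelineConfig(list(preprocessOp("median", 3), preprocessOp("opening", 3)))
#' @export
pipelineConfig <- function(preprocessing = list(), edgeDetector = "none",
                           thresholdMethod = "otsu", fixedLevel = 128,
                           invert = FALSE, blobFilters = list()) {
  new("PipelineConfig", preprocessing = preprocessing,
      edgeDetector = edgeDetector, thresholdMethod = thresholdMethod,
      fixedLevel = fixedLevel, invert = invert, blobFilters = blobFilters)
}

#' One preprocessing operation
#'
#' @param op one of `"average"`, `"median"`, `"laplacian"`, `"sharpen"`,
#'   `"custom_mask"`, `"dilation"`, `"erosion"`, `"opening"`, `"closing"`.
#' @param size odd kernel size (ignored by `laplacian`/`sharpen`, which are
#'   3x3, and by `custom_mask`).
#' @param iterations number of times the operation is applied (>= 1).
#' @param mask convolution kernel for `"custom_mask"` (odd 3x3/5x5/7x7).
#' @return a list usable in [pipelineConfig]'s `preprocessing`.
#' @export
preprocessOp <- function(op, size = 3, iterations = 1, mask = NULL) {
  list(op = op, size = size, iterations = iterations, mask = mask)
}

setMethod("show", "PipelineConfig", function(object) {
  ops <- vapply(object@preprocessing, function(o) o$op, "")
  cat(sprintf("PipelineConfig: [%s] -> %s threshold%s; %d blob filter bound(s)\n",
              paste(ops, collapse = ", "), object@thresholdMethod,
              if (object@invert) " (inverted polarity)" else "",
              length(object@blobFilters)))
})

convolve3 <- function(img, kern) {
  e <- EBImage::filter2(toEBI(img), kern, boundary = "replicate")
  t(as.matrix(EBImage::imageData(e))) * 255   # may be out of [0,255]; caller clips
}

#' Apply the configured preprocessing chain to an image
#'
#' Operations run in the configured order, each repeated `iterations`
#' times.  Smoothing/derivative ops (`average`, `median`, `laplacian`,
#' `sharpen`, `custom_mask`) are convolutions with replicated borders; the
#' Laplacian is the 4-neighbor kernel and its magnitude-shifted output is
#' clipped to 0-255.  Morphology (`dilation`, `erosion`, `opening`,
#' `closing`) uses a box structuring element of the given odd size.
#' Output has the input's dimensions and 8-bit range.
#'
#' @param img integer matrix `[y, x]`, 0-255.
#' @param config a [PipelineConfig-class] (its `preprocessing` is used).
#' @return processed image, same dimensions, 0-255 integer matrix.
#' @export
applyPreprocessing <- function(img, config) {
  validObject(config)
  out <- img
  for (opc in config@preprocessing) {
    it <- if (is.null(opc$iterations)) 1L else opc$iterations
    s <- if (is.null(opc$size)) 3L else as.integer(opc$size)
    for (i in seq_len(it)) out <- applyOneOp(out, opc$op, s, opc$mask)
  }
  clip255(out)
}

applyOneOp <- function(img, op, s, mask) {
  switch(op,
    average = clip255(convolve3(img, matrix(1 / s^2, s, s))),
    median = {
      e <- EBImage::medianFilter(toEBI(img), size = max(1L, (s - 1L) %/% 2L))
      fromEBI(e)
    },
    laplacian = clip255(abs(convolve3(img,
      matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)))),
    sharpen = clip255(convolve3(img,
      matrix(c(0, -1, 0, -1, 5, -1, 0, -1, 0), 3, 3))),
    custom_mask = clip255(convolve3(img, mask)),
    dilation = fromEBI(EBImage::dilate(toEBI(img), EBImage::makeBrush(s, "box"))),
    erosion = fromEBI(EBImage::erode(toEBI(img), EBImage::makeBrush(s, "box"))),
    opening = fromEBI(EBImage::opening(toEBI(img), EBImage::makeBrush(s, "box"))),
    closing = fromEBI(EBImage::closing(toEBI(img), EBImage::makeBrush(s, "box"))),
    stop("unknown preprocessing op: ", op)
  )
}

#' Edge-magnitude image (Roberts or Sobel)
#'
#' Gradient magnitude, clipped to 0-255.  Provided as optional
#' preprocessing; the segmentation mask always comes from thresholding.
#'
#' @param img integer matrix 0-255.
#' @param detector `"roberts"` or `"sobel"`.
#' @return edge-magnitude image, 0-255.
#' @export
edgeMagnitude <- function(img, detector = c("sobel", "roberts")) {
  detector <- match.arg(detector)
  if (detector == "sobel") {
    kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
    ky <- t(kx)
  } else {
    kx <- matrix(c(0, 0, 0, 0, 1, 0, 0, 0, -1), 3, 3)
    ky <- matrix(c(0, 0, 0, 0, 0, 1, 0, -1, 0), 3, 3)
  }
  gx <- convolve3(img, kx); gy <- convolve3(img, ky)
  clip255(sqrt(gx^2 + gy^2))
}

# ---- histogram thresholding -------------------------------------------------

grayHistogram <- function(img) {
  v <- as.integer(round(img))
  if (any(v < 0 | v > 255)) stop("gray levels must lie within [0, 255]")
  tabulate(v + 1L, 256L)
}

checkThresholdable <- function(h) {
  if (sum(h > 0) < 2)
    stop("image has fewer than 2 distinct gray levels; cannot threshold")
}

# All three methods scan candidate levels t = 0..254 (foreground = pixels
# > t), skip candidates with an empty class, and break ties toward the
# lowest optimal level.
bestLevel <- function(crit, valid, maximize) {
  if (!maximize) crit <- -crit
  crit[!valid] <- -Inf
  if (all(!is.finite(crit))) stop("no admissible threshold level")
  which.max(crit) - 1L    # first max = lowest level
}

#' Otsu threshold level
#'
#' Level maximizing the between-class variance of the 256-bin gray
#' histogram; foreground is the set of pixels strictly above the level.
#' Ties break toward the lowest level.  Constant images are an error.
#'
#' @param img integer matrix (or vector) of gray values 0-255.
#' @return integer level in 0..254.
#' @export
thresholdOtsu <- function(img) {
  h <- grayHistogram(img); checkThresholdable(h)
  n <- sum(h); p <- h / n; l <- 0:255
  w <- cumsum(p)[1:255]
  m <- cumsum(p * l)[1:255]
  mT <- sum(p * l)
  c0 <- cumsum(h)[1:255]
  valid <- c0 > 0 & c0 < n
  sb <- (mT * w - m)^2 / (w * (1 - w))
  bestLevel(sb, valid, maximize = TRUE)
}

#' Kapur (maximum entropy) threshold level
#'
#' Level maximizing the sum of the background and foreground Shannon class
#' entropies of the gray histogram.  Same candidate scan, empty-class
#' skipping and tie rule as [thresholdOtsu].
#'
#' @inheritParams thresholdOtsu
#' @return integer level in 0..254.
#' @export
thresholdKapur <- function(img) {
  h <- grayHistogram(img); checkThresholdable(h)
  n <- sum(h); p <- h / n
  plogp <- ifelse(p > 0, p * log(p), 0)
  Hc <- cumsum(-plogp)
  HT <- Hc[256]
  P0 <- cumsum(p)[1:255]; P1 <- 1 - P0
  c0 <- cumsum(h)[1:255]
  valid <- c0 > 0 & c0 < n
  H0 <- ifelse(valid, log(P0) + Hc[1:255] / P0, NA_real_)
  H1 <- ifelse(valid, log(P1) + (HT - Hc[1:255]) / P1, NA_real_)
  crit <- H0 + H1
  crit[!valid] <- -Inf
  bestLevel(crit, valid, maximize = TRUE)
}

#' Kittler-Illingworth (minimum error) threshold level
#'
#' Level minimizing the Kittler-Illingworth criterion
#' `J(t) = 1 + 2*(P0*log(s0) + P1*log(s1)) - 2*(P0*log(P0) + P1*log(P1))`,
#' with class proportions `P` and class gray-level standard deviations
#' `s`.  Class variances are floored at 1/12 (the quantization-noise
#' variance of integer gray levels) so single-level classes stay
#' well-defined; candidates with an empty class are skipped.  Same
#' candidate scan and tie rule as [thresholdOtsu].
#'
#' @inheritParams thresholdOtsu
#' @return integer level in 0..254.
#' @export
thresholdKittler <- function(img) {
  h <- grayHistogram(img); checkThresholdable(h)
  n <- sum(h); l <- 0:255
  c0 <- cumsum(h)[1:255]; c1 <- n - c0
  m0 <- cumsum(h * l)[1:255]; mT <- sum(h * l)
  q0 <- cumsum(h * l^2)[1:255]; qT <- sum(h * l^2)
  valid <- c0 > 0 & c1 > 0
  P0 <- c0 / n; P1 <- c1 / n
  mu0 <- m0 / c0; mu1 <- (mT - m0) / c1
  v0 <- pmax(q0 / c0 - mu0^2, 1 / 12)
  v1 <- pmax((qT - q0) / c1 - mu1^2, 1 / 12)
  J <- 1 + 2 * (P0 * log(sqrt(v0)) + P1 * log(sqrt(v1))) -
    2 * (P0 * log(P0) + P1 * log(P1))
  bestLevel(J, valid, maximize = FALSE)
}

thresholdLevel <- function(img, config) {
  switch(config@thresholdMethod,
    otsu = thresholdOtsu(img),
    kapur = thresholdKapur(img),
    kittler = thresholdKittler(img),
    fixed = config@fixedLevel,
    stop("unknown threshold method"))
}

# ---- connected components ---------------------------------------------------

# 8-connected labeling: EBImage::bwlabel (4-connected) + union-find merge of
# labels touching diagonally; labels re-assigned in raster order (row-major
# by first pixel).
label8 <- function(bin) {
  lab <- t(as.matrix(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(bin * 1))))))
  nl <- max(lab)
  if (nl == 0) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  parent <- seq_len(nl)
  findRoot <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unionPairs <- function(a, b) {
    keep <- a > 0 & b > 0 & a != b
    for (k in which(keep)) {
      ra <- findRoot(a[k]); rb <- findRoot(b[k])
      if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    }
  }
  if (H > 1 && W > 1) {
    unionPairs(lab[-H, -W], lab[-1, -1])   # down-right diagonal
    unionPairs(lab[-H, -1], lab[-1, -W])   # down-left diagonal
  }
  roots <- vapply(seq_len(nl), findRoot, 1L)
  merged <- matrix(0L, H, W)
  fg <- lab > 0
  merged[fg] <- roots[lab[fg]]
  # raster-order relabeling by first pixel (smallest y, then x)
  idx <- which(fg, arr.ind = TRUE)
  key <- (idx[, 1] - 1) * W + (idx[, 2] - 1)
  firstKey <- tapply(key, merged[fg], min)
  ord <- order(firstKey)
  remap <- integer(nl)
  remap[as.integer(names(firstKey))[ord]] <- seq_along(ord)
  merged[fg] <- remap[merged[fg]]
  merged
}

#' Extract blobs (connected components) from a binary image
#'
#' 8-connected foreground components, optionally restricted to a
#' rectangular ROI, each with the full shape-feature set.  Labels are
#' assigned in raster order of each blob's first pixel.  The sum of blob
#' areas equals the (ROI-restricted) foreground pixel count.
#'
#' @param bin logical (or 0/1) matrix `[y, x]`.
#' @param roi optional rectangle `(xmin, ymin, xmax, ymax)`, 0-based
#'   inclusive, within the image bounds.
#' @param scale optional isotropic mm/pixel scale passed to
#'   [computeShape].
#' @return data frame with one row per blob: `label`, `area`, `perimeter`,
#'   `length`, `angle`, `cx`, `cy`, `compactness`, `xmin`, `ymin`, `xmax`,
#'   `ymax`, `npix`, `degenerate`, plus a `pixels` list-column of linear
#'   indices into the full image matrix.
#' @export
extractBlobs <- function(bin, roi = NULL, scale = 1) {
  bin <- bin > 0
  H <- nrow(bin); W <- ncol(bin)
  off <- c(0, 0)
  sub <- bin
  if (!is.null(roi)) {
    roi <- round(roi)
    if (roi[1] < 0 || roi[2] < 0 || roi[3] > W - 1 || roi[4] > H - 1 ||
        roi[1] > roi[3] || roi[2] > roi[4])
      stop("roi outside image bounds")
    sub <- bin[(roi[2]:roi[4]) + 1, (roi[1]:roi[3]) + 1, drop = FALSE]
    off <- roi[1:2]
  }
  lab <- label8(sub)
  nl <- max(lab)
  if (nl == 0) {
    return(data.frame(label = integer(0), area = numeric(0),
                      perimeter = numeric(0), length = numeric(0),
                      angle = numeric(0), cx = numeric(0), cy = numeric(0),
                      compactness = numeric(0), xmin = numeric(0),
                      ymin = numeric(0), xmax = numeric(0), ymax = numeric(0),
                      npix = integer(0), degenerate = logical(0)))
  }
  rows <- vector("list", nl)
  pixels <- vector("list", nl)
  for (k in seq_len(nl)) {
    mk <- lab == k
    f <- computeShape(mk, scale = scale, offset = off)
    rows[[k]] <- data.frame(label = k, area = f$area, perimeter = f$perimeter,
                            length = f$length, angle = f$angle, cx = f$cx,
                            cy = f$cy, compactness = f$compactness,
                            xmin = f$bbox[1], ymin = f$bbox[2],
                            xmax = f$bbox[3], ymax = f$bbox[4],
                            npix = f$npix, degenerate = f$degenerate)
    idx <- which(mk, arr.ind = TRUE)
    pixels[[k]] <- (idx[, 2] - 1 + off[1]) * H + (idx[, 1] + off[2])  # full-image linear index
  }
  out <- do.call(rbind, rows)
  out$pixels <- pixels
  out
}

#' Filter blobs by feature bounds
#'
#' Keeps the blobs satisfying every configured min/max bound on area,
#' compactness, length and perimeter; order is preserved.  Idempotent; the
#' output is always a subset of the input.
#'
#' @param blobs data frame from [extractBlobs].
#' @param filters named list of bounds (`areaMin`, `areaMax`,
#'   `compactnessMin`, `compactnessMax`, `lengthMin`, `lengthMax`,
#'   `perimeterMin`, `perimeterMax`); any subset may be given.
#' @return the filtered blob data frame.
#' @export
filterBlobs <- function(blobs, filters = list()) {
  if (!length(filters) || !nrow(blobs)) return(blobs)
  for (q in c("area", "compactness", "length", "perimeter")) {
    lo <- filters[[paste0(q, "Min")]]; hi <- filters[[paste0(q, "Max")]]
    if (!is.null(lo) && !is.null(hi) && lo > hi)
      stop(sprintf("%s filter has min > max", q))
  }
  keep <- rep(TRUE, nrow(blobs))
  for (q in c("area", "compactness", "length", "perimeter")) {
    lo <- filters[[paste0(q, "Min")]]; hi <- filters[[paste0(q, "Max")]]
    if (!is.null(lo)) keep <- keep & blobs[[q]] >= lo
    if (!is.null(hi)) keep <- keep & blobs[[q]] <= hi
  }
  blobs[keep, , drop = FALSE]
}

#' Run the full segmentation chain on one frame
#'
#' Preprocessing, optional polarity inversion, optional edge-magnitude
#' transform, histogram thresholding (computed on the ROI region when a
#' ROI is given), blob extraction and blob filtering.
#'
#' @param img integer matrix `[y, x]`, 0-255.
#' @param config a [PipelineConfig-class].
#' @param roi optional rectangle `(xmin, ymin, xmax, ymax)` restricting
#'   analysis.
#' @param scale optional mm/pixel scale for the blob features.
#' @return list with `binary` (full-size logical mask, FALSE outside the
#'   ROI), `level` (threshold used) and `blobs` (filtered blob table).
#' @export
segmentFrame <- function(img, config, roi = NULL, scale = 1) {
  validObject(config)
  pre <- applyPreprocessing(img, config)
  if (config@invert) pre <- 255 - pre
  if (config@edgeDetector != "none") pre <- edgeMagnitude(pre, config@edgeDetector)
  region <- if (is.null(roi)) pre else
    pre[(roi[2]:roi[4]) + 1, (roi[1]:roi[3]) + 1, drop = FALSE]
  level <- thresholdLevel(region, config)
  bin <- matrix(FALSE, nrow(img), ncol(img))
  if (is.null(roi)) {
    bin <- pre > level
  } else {
    bin[(roi[2]:roi[4]) + 1, (roi[1]:roi[3]) + 1] <- region > level
  }
  blobs <- filterBlobs(extractBlobs(bin, roi = roi, scale = scale),
                       config@blobFilters)
  list(binary = bin, level = level, blobs = blobs)
}
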