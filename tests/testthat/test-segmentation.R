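test_that("thresholding separates a two-level image identically across methods", {
  img <- matrix(c(50, 50, 50, 200, 200, 200), 2)
  for (fn in list(thresholdOtsu, thresholdKapur, thresholdKittler)) {
    lvl <- fn(img)
    expect_gte(lvl, 50)
    expect_lte(lvl, 199)
    expect_identical(img > lvl, img == 200)
  }
  expect_error(thresholdOtsu(matrix(7, 3, 3)), "distinct")
  expect_error(thresholdKapur(matrix(0, 2, 2)), "distinct")
  expect_error(thresholdKittler(matrix(255, 2, 2)), "distinct")
})

test_that("all three thresholds equal an exhaustive criterion scan on random histograms", {
  set.seed(101)
  for (i in 1:100) {
    # random bimodal-ish small images covering sparse and dense histograms
    n <- sample(30:200, 1)
    m1 <- sample(0:120, 1); m2 <- m1 + sample(30:130, 1)
    v <- c(round(rnorm(n, m1, sample(2:25, 1))),
           round(rnorm(n, m2, sample(2:25, 1))))
    v <- pmin(pmax(v, 0), 255)
    if (length(unique(v)) < 2) next
    img <- matrix(v, 1)
    expect_identical(thresholdOtsu(img), oracleOtsu(img))
    expect_identical(thresholdKapur(img), oracleKapur(img))
    expect_identical(thresholdKittler(img), oracleKittler(img))
  }
})

test_that("package Otsu agrees with EBImage's on a continuous image", {
  set.seed(5)
  v <- round(pmin(pmax(c(rnorm(5000, 70, 12), rnorm(5000, 180, 18)), 0), 255))
  img <- matrix(v, 100)
  ours <- thresholdOtsu(img)
  ref <- EBImage::otsu(EBImage::Image(t(img) / 255), range = c(0, 1), levels = 256) * 255
  # conventions differ by at most one bin boundary
  expect_lte(abs(ours - ref), 1)
})

test_that("Kittler lands near the analytic minimum-error boundary of a Gaussian mixture", {
  set.seed(77)
  mu1 <- 80; mu2 <- 170; s <- 14   # equal variances, equal priors
  v <- round(c(rnorm(20000, mu1, s), rnorm(20000, mu2, s)))
  img <- matrix(pmin(pmax(v, 0), 255), 200)
  # equal-prior equal-variance mixture: Bayes boundary is the midpoint
  expect_lte(abs(thresholdKittler(img) - (mu1 + mu2) / 2), 2)
})

test_that("noise-free synthetic frames segment to the ground-truth pixel area", {
  org <- organModel(initialSemiaxes = c(18, 12), growthRate = c(0, 0),
                    nutationAmplitude = 0, baseAngle = 40, center = c(70, 55))
  il <- illuminationModel(noiseSd = 0, jumpEmulation = FALSE)
  r <- renderFrame(org, il, t = 0, period = "day", size = c(110, 140), seed = 1)
  for (meth in c("otsu", "kapur", "kittler")) {
    seg <- segmentFrame(r$image, pipelineConfig(thresholdMethod = meth))
    expect_identical(nrow(seg$blobs), 1L)
    expect_equal(seg$blobs$area, r$truth$areaPx)
    expect_lt(abs(seg$blobs$cx - r$truth$cx), 0.5)
    expect_lt(abs(seg$blobs$cy - r$truth$cy), 0.5)
    expect_lt(abs(seg$blobs$angle - r$truth$angle), 2)
  }
})

test_that("preprocessing identity, morphology and median behave as defined", {
  set.seed(3)
  img <- matrix(sample(0:255, 30 * 40, TRUE), 30)
  expect_identical(applyPreprocessing(img, pipelineConfig()), img)

  # opening removes an isolated foreground pixel
  spot <- matrix(0, 21, 21); spot[11, 11] <- 255
  opened <- applyPreprocessing(spot, pipelineConfig(list(preprocessOp("opening", 3))))
  expect_true(all(opened == 0))
  # erosion then dilation equals opening
  ed <- applyPreprocessing(spot, pipelineConfig(list(
    preprocessOp("erosion", 3), preprocessOp("dilation", 3))))
  expect_identical(ed, opened)

  # median vs brute force (interior)
  base <- matrix(120, 25, 25)
  salt <- cbind(c(5, 12, 18), c(7, 13, 20))
  base[salt] <- 255
  med <- applyPreprocessing(base, pipelineConfig(list(preprocessOp("median", 3))))
  ref <- oracleMedian3(base)
  expect_equal(med[2:24, 2:24], ref[2:24, 2:24], ignore_attr = TRUE)
  expect_true(all(med[salt] == 120))
})

test_that("pipeline configuration rejects invalid setups", {
  expect_error(pipelineConfig(rep(list(preprocessOp("median")), 5)), "4")
  expect_error(pipelineConfig(list(preprocessOp("average", size = 4))), "odd")
  expect_error(pipelineConfig(list(preprocessOp("median", iterations = 0))), ">= 1")
  expect_error(pipelineConfig(list(preprocessOp("custom_mask", mask = matrix(1, 2, 2)))),
               "odd")
  expect_error(pipelineConfig(blobFilters = list(areaMin = 10, areaMax = 5)),
               "min > max")
})

test_that("blob extraction partitions the foreground under 8-connectivity", {
  # two disjoint squares
  b <- matrix(FALSE, 20, 20)
  b[3:5, 3:5] <- TRUE; b[10:12, 14:16] <- TRUE
  blobs <- extractBlobs(b)
  expect_identical(nrow(blobs), 2L)
  expect_equal(blobs$area, c(9, 9))
  # diagonal chain is one component
  d <- matrix(FALSE, 10, 10); d[cbind(2:8, 2:8)] <- TRUE
  expect_identical(nrow(extractBlobs(d)), 1L)
  # empty image
  expect_identical(nrow(extractBlobs(matrix(FALSE, 5, 5))), 0L)
  # partition property on random binary images
  set.seed(9)
  for (i in 1:5) {
    m <- matrix(runif(40 * 40) < 0.25, 40)
    bl <- extractBlobs(m)
    expect_equal(sum(bl$area), sum(m))
    expect_false(anyDuplicated(unlist(bl$pixels)) > 0)
  }
})

test_that("blob labels come in raster order and ROIs restrict extraction", {
  b <- matrix(FALSE, 20, 30)
  b[12:14, 2:4] <- TRUE    # lower-left blob
  b[2:4, 20:22] <- TRUE    # upper-right blob (first in raster order)
  bl <- extractBlobs(b)
  expect_equal(bl$ymin, c(1, 11))  # raster: top blob labelled 1
  roi <- c(15, 0, 29, 19)
  blR <- extractBlobs(b, roi = roi)
  expect_identical(nrow(blR), 1L)
  expect_equal(blR$xmin, 19)
  expect_error(extractBlobs(b, roi = c(-1, 0, 5, 5)), "bounds")
})

test_that("blob filtering keeps interval members, preserves order, and is idempotent", {
  b <- matrix(FALSE, 40, 120)
  b[2:3, 2:3] <- TRUE                        # area 4
  b[10:16, 10:16] <- TRUE                    # area 49
  b[25:39, 30:110] <- TRUE                   # area 1215
  blobs <- extractBlobs(b)
  expect_identical(nrow(filterBlobs(blobs)), 3L)
  f <- filterBlobs(blobs, list(areaMin = 10, areaMax = 100))
  expect_equal(f$area, 49)
  expect_identical(filterBlobs(f, list(areaMin = 10, areaMax = 100)), f)
  expect_error(filterBlobs(blobs, list(lengthMin = 9, lengthMax = 2)), "min > max")

  # compactness bound separates a disc from an elongated bar
  disc <- discMask(12); bar <- barMask(30, 3, 20)
  n <- max(nrow(disc), nrow(bar))
  scene <- matrix(FALSE, n, 2 * n + 10)
  scene[1:nrow(disc), 1:ncol(disc)] <- disc
  scene[1:nrow(bar), (n + 11):(n + 10 + ncol(bar))] <- bar
  blobs2 <- extractBlobs(scene)
  kept <- filterBlobs(blobs2, list(compactnessMax = 1.3))
  expect_identical(nrow(kept), 1L)
  expect_lt(kept$compactness, 1.1)
})

test_that("polarity inversion and fixed thresholds are honoured", {
  img <- matrix(200, 30, 30); img[10:20, 10:20] <- 60  # dark organ
  seg <- segmentFrame(img, pipelineConfig(invert = TRUE))
  expect_identical(nrow(seg$blobs), 1L)
  expect_equal(seg$blobs$area, 121)
  segF <- segmentFrame(img, pipelineConfig(thresholdMethod = "fixed", fixedLevel = 100))
  expect_equal(sum(segF$binary), sum(img > 100))
})
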