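test_that("grid detection finds all circles at sub-pixel accuracy", {
  tg <- calibrationTarget()
  g <- renderCalibrationGrid(tg, scaleMmPerPx = 0.25)
  cen <- detectGridCircles(g$image, tg)
  expect_identical(nrow(cen), 100L)
  expect_lt(max(abs(cen$x - g$centers$x)), 0.5)
  expect_lt(max(abs(cen$y - g$centers$y)), 0.5)
  # blank image: no circles
  expect_error(detectGridCircles(matrix(200, 50, 50), tg), "0 circles")
  expect_error(detectGridCircles(matrix(c(10, 200), 40, 40), tg), "expected 100")
})

test_that("polarity is auto-detected (bright circles on dark background)", {
  tg <- calibrationTarget(rows = 4, cols = 4)
  g <- renderCalibrationGrid(tg, scaleMmPerPx = 0.5, fg = 220, bg = 30)
  cen <- detectGridCircles(g$image, tg)
  expect_identical(nrow(cen), 16L)
  expect_lt(max(abs(cen$x - g$centers$x)), 0.5)
})

test_that("plane-scale fitting recovers the rendering scale and circle radius", {
  tg <- calibrationTarget()
  for (s in c(0.1, 0.25, 0.4)) {
    g <- renderCalibrationGrid(tg, scaleMmPerPx = s)
    cen <- detectGridCircles(g$image, tg)
    pc <- fitPlaneScale(cen, tg, distanceMm = 100)
    expect_equal(pc@scaleX, s, tolerance = 0.01)
    expect_equal(pc@scaleY, s, tolerance = 0.01)
    expect_lt(pc@residualMm, 0.1)
    rMm <- mean(cen$radiusPx) * mean(c(pc@scaleX, pc@scaleY))
    expect_equal(rMm, tg@circleRadiusMm, tolerance = 0.02 * tg@circleRadiusMm)
  }
})

test_that("exact synthetic centers give exact scales and zero residual", {
  tg <- calibrationTarget(rows = 5, cols = 5, circleRadiusMm = 2, pitchMm = 10)
  cen <- expand.grid(x = 100 + (0:4) * 40, y = 50 + (0:4) * 40)
  cen <- cen[order(cen$y, cen$x), ]
  pc <- fitPlaneScale(cen, tg)
  expect_equal(pc@scaleX, 0.25)
  expect_equal(pc@scaleY, 0.25)
  expect_equal(pc@residualMm, 0, tolerance = 1e-9)
  expect_error(fitPlaneScale(cen[1:10, ], tg), "rows x cols")
})

test_that("scale survives bounded center perturbations", {
  tg <- calibrationTarget(rows = 10, cols = 10, circleRadiusMm = 2, pitchMm = 10)
  base <- expand.grid(x = 20 + (0:9) * 40, y = 20 + (0:9) * 40)
  base <- base[order(base$y, base$x), ]
  set.seed(33)
  for (i in 1:10) {
    cen <- base
    cen$x <- cen$x + runif(100, -0.5, 0.5)
    cen$y <- cen$y + runif(100, -0.5, 0.5)
    pc <- fitPlaneScale(cen, tg)
    expect_equal(pc@scaleX, 0.25, tolerance = 0.01)
    expect_equal(pc@scaleY, 0.25, tolerance = 0.01)
  }
})

test_that("round trip render->detect->fit holds over a 10x scale range", {
  tg <- calibrationTarget(rows = 4, cols = 4)
  for (s in c(0.08, 0.25, 0.8)) {
    g <- renderCalibrationGrid(tg, scaleMmPerPx = s)
    pc <- fitPlaneScale(detectGridCircles(g$image, tg), tg)
    expect_equal(pc@scaleX, s, tolerance = 0.01)
  }
})

test_that("pinhole-rendered planes give scales linear in distance", {
  tg <- calibrationTarget(rows = 4, cols = 4)
  k <- 0.002  # mm/px per mm of distance
  d <- c(100, 150, 200, 250)
  fitted <- vapply(d, function(di) {
    g <- renderCalibrationGrid(tg, scaleMmPerPx = k * di)
    fitPlaneScale(detectGridCircles(g$image, tg), tg)@scaleX
  }, 0)
  fit <- lm(fitted ~ d)
  expect_gt(summary(fit)$r.squared, 0.999)
  expect_equal(unname(coef(fit)[2]), k, tolerance = 0.01)
})

test_that("distance queries interpolate linearly and refuse extrapolation", {
  m <- calibrationModel(list(
    new("PlaneCalibration", distanceMm = 100, scaleX = 0.2, scaleY = 0.2,
        residualMm = 0),
    new("PlaneCalibration", distanceMm = 110, scaleX = 0.22, scaleY = 0.22,
        residualMm = 0)))
  expect_equal(unname(scaleAtDistance(m, 100)), c(0.2, 0.2))
  expect_equal(unname(scaleAtDistance(m, 105)), c(0.21, 0.21))
  expect_error(scaleAtDistance(m, 99), "outside")
  expect_error(scaleAtDistance(m, 111), "outside")
  expect_error(calibrationModel(list(
    new("PlaneCalibration", distanceMm = 100, scaleX = 0.2, scaleY = 0.2,
        residualMm = 0),
    new("PlaneCalibration", distanceMm = 100, scaleX = 0.3, scaleY = 0.3,
        residualMm = 0))), "duplicate")
})

test_that("calibration models persist as JSON", {
  m <- calibrationModel(lapply(c(100, 110, 120), function(d)
    new("PlaneCalibration", distanceMm = d, scaleX = 0.002 * d,
        scaleY = 0.002 * d, residualMm = 0.01)))
  f <- tempfile(fileext = ".json")
  writeCalibrationJson(m, f)
  m2 <- readCalibrationJson(f)
  expect_equal(calibrationPlanes(m2), calibrationPlanes(m))
})
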