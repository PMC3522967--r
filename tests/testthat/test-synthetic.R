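test_that("rendered frames match the analytic organ geometry", {
  org <- organModel(initialSemiaxes = c(10, 10), growthRate = c(0, 0),
                    nutationAmplitude = 0, baseAngle = 0, center = c(50, 40))
  il <- illuminationModel(noiseSd = 0, jumpEmulation = FALSE)
  r <- renderFrame(org, il, t = 0, period = "day", size = c(81, 101), seed = 1)
  expect_equal(r$truth$areaTrue, pi * 100)
  expect_equal(r$truth$areaPx, sum(r$image > il@dayBg))
  expect_equal(c(r$truth$cx, r$truth$cy), c(50, 40))
  # identity case: no growth, no nutation -> identical truth at t=0 and t=1
  r1 <- renderFrame(org, il, t = 1, period = "day", size = c(81, 101), seed = 1)
  expect_equal(r1$truth[, !(names(r1$truth) %in% "t")],
               r$truth[, !(names(r$truth) %in% "t")])
})

test_that("segmenting a rendered rotated ellipse recovers its angle within 2 degrees", {
  org <- organModel(initialSemiaxes = c(20, 10), growthRate = c(0, 0),
                    nutationAmplitude = 0, baseAngle = 30, center = c(60, 50))
  il <- illuminationModel(noiseSd = 0, jumpEmulation = FALSE)
  r <- renderFrame(org, il, t = 0, period = "day", size = c(100, 120), seed = 1)
  expect_equal(r$truth$angle, 30)
  seg <- segmentFrame(r$image, pipelineConfig())
  expect_lt(abs(seg$blobs$angle - 30), 2)
})

test_that("superellipse rendering matches its closed-form area", {
  org <- organModel(shapeKind = "superellipse", exponent = 4,
                    initialSemiaxes = c(22, 15), growthRate = c(0, 0),
                    nutationAmplitude = 0, baseAngle = 0, center = c(50, 45))
  il <- illuminationModel(noiseSd = 0, jumpEmulation = FALSE)
  r <- renderFrame(org, il, t = 0, period = "day", size = c(95, 105), seed = 1)
  aAnalytic <- 4 * 22 * 15 * gamma(1.25)^2 / gamma(1.5)
  expect_equal(r$truth$areaTrue, aAnalytic)
  # flat-sided superellipses carry a larger pixel-center digitization bias
  # than ellipses; a few percent at this size
  expect_equal(r$truth$areaPx / aAnalytic, 1, tolerance = 0.03)
})

test_that("out-of-frame organs and invalid gray levels are rejected", {
  il <- illuminationModel(noiseSd = 0)
  big <- organModel(initialSemiaxes = c(60, 40), center = c(30, 30))
  expect_error(renderFrame(big, il, t = 0, period = "day", size = c(80, 80)),
               "out of frame")
  grower <- organModel(initialSemiaxes = c(20, 15), growthRate = c(2, 2),
                       center = c(60, 60))
  plan <- experimentPlan(days = 1, imagesPerHour = 2)
  expect_error(simulateSequence(grower, il, plan, size = c(130, 130)),
               "out of frame")
  expect_error(illuminationModel(dayBg = -5), "\\[0, 255\\]")
  expect_error(illuminationModel(dayBg = 100, dayFg = 110), "contrast")
  expect_error(organModel(initialSemiaxes = c(0, 5)), "positive")
})

test_that("sequences are deterministic and follow the schedule's periods", {
  sq1 <- smallSequence(days = 1, imagesPerHour = 1, noiseSd = 4, seed = 21)
  sq2 <- smallSequence(days = 1, imagesPerHour = 1, noiseSd = 4, seed = 21)
  expect_identical(sq1@frames, sq2@frames)      # bitwise identical
  expect_identical(groundTruth(sq1), groundTruth(sq2))
  expect_identical(length(sq1), 24L)
  expect_identical(sum(scheduleTable(sq1)$period == "night"), 8L)
  sq3 <- smallSequence(days = 1, imagesPerHour = 1, noiseSd = 4, seed = 22)
  expect_false(identical(sq1@frames, sq3@frames))
})

test_that("day and night frame means differ by the configured background offset", {
  il <- illuminationModel(noiseSd = 2, jumpEmulation = TRUE)
  org <- organModel(initialSemiaxes = c(10, 8), growthRate = c(0, 0),
                    nutationAmplitude = 0, center = c(60, 45))
  plan <- experimentPlan(days = 1, imagesPerHour = 1)
  sq <- simulateSequence(org, il, plan, seed = 2, size = c(90, 120))
  per <- scheduleTable(sq)$period
  mDay <- mean(vapply(sq@frames[per == "day"], mean, 0))
  mNight <- mean(vapply(sq@frames[per == "night"], mean, 0))
  # organ covers ~2% of the frame; pooled means are background-dominated
  expect_equal(mDay - mNight, il@dayBg - il@nightBg, tolerance = il@noiseSd + 3)
})

test_that("nutation amplitude is recoverable from the ground-truth centroid", {
  org <- organModel(initialSemiaxes = c(12, 9), growthRate = c(0, 0),
                    nutationAmplitude = 6, nutationPeriod = 12, center = c(60, 50))
  il <- illuminationModel(noiseSd = 0, jumpEmulation = FALSE)
  plan <- experimentPlan(days = 1, imagesPerHour = 1)
  sq <- simulateSequence(org, il, plan, seed = 1, size = c(100, 120))
  tru <- groundTruth(sq)
  mv <- motionVector(tru$cx, tru$cy)
  expect_equal(max(mv), 2 * 6, tolerance = 0.5)  # peak-to-origin swing
})

test_that("dawn pulses step the organ only at night-to-day transitions", {
  org <- organModel(initialSemiaxes = c(12, 9), growthRate = c(0, 0),
                    nutationAmplitude = 0, dawnPulsePx = 5, center = c(60, 50))
  il <- illuminationModel(noiseSd = 0, jumpEmulation = FALSE)
  plan <- experimentPlan(days = 2, imagesPerHour = 1)
  sq <- simulateSequence(org, il, plan, seed = 1, size = c(110, 120))
  tru <- groundTruth(sq)
  steps <- diff(tru$cy)
  dawn2 <- which(tru$transition == "T_nd")[2]   # second dawn = first pulse
  expect_equal(steps[dawn2 - 1], 5)
  expect_true(all(steps[-(dawn2 - 1)] == 0))
})

test_that("ground-truth areas are monotone when growth rates are non-negative", {
  sq <- smallSequence(days = 1, imagesPerHour = 2)
  expect_false(is.unsorted(groundTruth(sq)$areaTrue))
})
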