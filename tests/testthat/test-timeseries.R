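test_that("transition correction removes the jump and restores the period step", {
  # night [0,1,2,3], day starts at 10 rising by 1: jump 7, night step 1
  v <- c(0, 1, 2, 3, 10, 11, 12, 13)
  p <- rep(c("night", "day"), each = 4)
  expect_equal(correctTransitions(v, p), 0:7)
  # no jump: corrected == raw
  v2 <- 1:8
  expect_equal(correctTransitions(v2, p), v2)
})

test_that("correction preserves within-period differences bit-for-bit and accumulates offsets", {
  set.seed(15)
  p <- rep(rep(c("day", "night"), 3), each = 5)
  v <- cumsum(rnorm(30, 1, 0.3)) + 25 * (p == "night")   # jumps both ways
  corr <- correctTransitions(v, p)
  runId <- cumsum(c(TRUE, p[-1] != p[-30]))
  for (r in split(seq_along(p), runId)) {
    # exact up to the rounding of the single constant-offset addition
    expect_equal(diff(corr[r]), diff(v[r]), tolerance = 1e-12)
  }
  # corrected steps at transitions are period-step sized, not jump sized
  tix <- which(p[-1] != p[-30])
  expect_true(all(abs(diff(corr)[tix]) < 3))
  expect_true(any(abs(diff(v)[tix]) > 20))
})

test_that("correction refuses periods too short to estimate a step", {
  v <- c(1, 5, 6, 7)
  p <- c("night", "day", "day", "day")
  expect_error(correctTransitions(v, p), "fewer than 2")
  expect_error(correctTransitions(1:3, c("day", "day")), "same length")
})

test_that("accumulated growth sums positive increments from zero", {
  expect_equal(accumulateGrowth(c(5, 7, 6, 9)), c(0, 2, 2, 5))
  v <- c(2, 4, 4.5, 8)
  expect_equal(accumulateGrowth(v), v - v[1])            # monotone case
  set.seed(8)
  r <- cumsum(rnorm(50))
  acc <- accumulateGrowth(r)
  expect_equal(acc[1], 0)
  expect_false(is.unsorted(acc))
})

test_that("growth binarization flags interval increases above epsilon", {
  up <- seq(0, 30, length.out = 13)
  flat <- rep(5, 13)
  pat <- binarizeGrowth(up[1:12], flat[1:12], samplesPerInterval = 4)
  f <- patternFlags(pat)
  expect_equal(f$area, c(1, 1, 1))
  expect_equal(f$length, c(0, 0, 0))
  # invariant to adding a constant
  pat2 <- binarizeGrowth(up[1:12] + 100, flat[1:12] + 100, samplesPerInterval = 4)
  expect_equal(patternFlags(pat2)[-1], f[-1])
  expect_error(binarizeGrowth(up[1:3], flat[1:3], samplesPerInterval = 4),
               "shorter")
})

test_that("the cladode-style binary pattern counts length-only growth intervals", {
  area <- c(0,1,0,0,1,1,1,1,0,0,1,0,1,1,0,0,1,0,1,1,0)
  leng <- c(0,1,1,0,1,0,1,0,1,1,1,1,1,1,1,1,1,0,1,1,0)
  # build accumulated series realizing exactly these per-interval flags:
  # each interval is a block of m samples, growing within the block iff
  # its flag is 1, flat across block boundaries
  mkSeries <- function(flags, m = 4) {
    incr <- unlist(lapply(flags, function(fl) c(rep(10 * fl / (m - 1), m - 1), 0)))
    cumsum(c(0, incr))[seq_len(length(flags) * m)]
  }
  accA <- mkSeries(area); accL <- mkSeries(leng)
  pat <- binarizeGrowth(accA, accL, samplesPerInterval = 4)
  f <- patternFlags(pat)
  expect_equal(f$area, area)
  expect_equal(f$length, leng)
  expect_identical(sum(f$length == 1 & f$area == 0), 6L)  # decoupling events
})

mockTrack <- function(cx, cy, missing = rep(FALSE, length(cx)),
                      box = c(10, 10, 30, 30)) {
  n <- length(cx)
  f <- data.frame(frame = seq_len(n) - 1, instant = as.POSIXct(NA),
                  period = NA_character_, transition = NA_character_,
                  area = 100, perimeter = 40, length = 12, angle = 0,
                  cx = cx, cy = cy, compactness = 1.1, missing = missing)
  rois <- matrix(rep(box, each = n), n) + cbind(cx - cx[1], cy - cy[1],
                                                cx - cx[1], cy - cy[1])
  new("OrganTrack", features = f, rois = rois, mgx = 0, mgy = 0,
      config = pipelineConfig())
}

test_that("organ ranking keeps visible unoccluded organs and ranks by activity", {
  n <- 48
  t1 <- mockTrack(cx = 50 + 8 * sin(2 * pi * (1:n) / 12), cy = rep(40, n),
                  box = c(40, 30, 60, 50))
  t2 <- mockTrack(cx = 150 + 4 * sin(2 * pi * (1:n) / 12), cy = rep(40, n),
                  box = c(140, 30, 160, 50))
  rk <- rankOrgans(list(t1, t2))
  expect_true(all(rk$retained))
  expect_equal(rk$organ[rk$rank == 1], 1)   # double amplitude ranks first
  # single organ: retained, rank 1
  rk1 <- rankOrgans(list(t1))
  expect_true(rk1$retained)
  expect_equal(rk1$rank, 1L)
  expect_error(rankOrgans(list()), "empty")
})

test_that("occluded or invisible organs are discarded", {
  n <- 40
  a <- mockTrack(cx = rep(50, n), cy = rep(40, n), box = c(40, 30, 60, 50))
  b <- mockTrack(cx = rep(51, n), cy = rep(41, n), box = c(41, 31, 61, 51))
  rk <- rankOrgans(list(a, b))
  expect_true(any(!rk$retained))           # mutual >50% overlap every frame
  c_ <- mockTrack(cx = rep(120, n), cy = rep(40, n),
                  missing = c(rep(TRUE, 30), rep(FALSE, 10)),
                  box = c(110, 30, 130, 50))
  rk2 <- rankOrgans(list(a, c_))
  expect_false(rk2$retained[rk2$organ == 2])  # visibility 25% < 80%
})
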