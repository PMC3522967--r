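# Independent brute-force oracles for the histogram thresholding criteria.
# Deliberately naive: per-candidate loops computing each criterion from its
# definition, no shared code with the package's vectorized implementations.

oracleScan <- function(img, criterion, maximize) {
  v <- as.integer(round(img))
  h <- tabulate(v + 1L, 256L)
  best <- NULL; bestCrit <- if (maximize) -Inf else Inf
  for (t in 0:254) {
    nb <- sum(h[1:(t + 1)]); nf <- sum(h) - nb
    if (nb == 0 || nf == 0) next
    cr <- criterion(h, t)
    if (is.na(cr)) next
    better <- if (maximize) cr > bestCrit + 1e-12 else cr < bestCrit - 1e-12
    if (better) { bestCrit <- cr; best <- t }
  }
  best
}

oracleOtsu <- function(img) {
  oracleScan(img, function(h, t) {
    n <- sum(h); l <- 0:255
    ib <- 1:(t + 1); if_ <- (t + 2):256
    w0 <- sum(h[ib]) / n; w1 <- 1 - w0
    mu0 <- sum(h[ib] * l[ib]) / sum(h[ib])
    mu1 <- sum(h[if_] * l[if_]) / sum(h[if_])
    w0 * w1 * (mu0 - mu1)^2
  }, maximize = TRUE)
}

oracleKapur <- function(img) {
  oracleScan(img, function(h, t) {
    n <- sum(h)
    p <- h / n
    ib <- 1:(t + 1); if_ <- (t + 2):256
    P0 <- sum(p[ib]); P1 <- sum(p[if_])
    ent <- function(ps, P) {
      ps <- ps[ps > 0] / P
      -sum(ps * log(ps))
    }
    ent(p[ib], P0) + ent(p[if_], P1)
  }, maximize = TRUE)
}

oracleKittler <- function(img) {
  oracleScan(img, function(h, t) {
    n <- sum(h); l <- 0:255
    ib <- 1:(t + 1); if_ <- (t + 2):256
    P0 <- sum(h[ib]) / n; P1 <- sum(h[if_]) / n
    mu0 <- sum(h[ib] * l[ib]) / sum(h[ib])
    mu1 <- sum(h[if_] * l[if_]) / sum(h[if_])
    v0 <- max(sum(h[ib] * (l[ib] - mu0)^2) / sum(h[ib]), 1 / 12)
    v1 <- max(sum(h[if_] * (l[if_] - mu1)^2) / sum(h[if_]), 1 / 12)
    1 + 2 * (P0 * log(sqrt(v0)) + P1 * log(sqrt(v1))) -
      2 * (P0 * log(P0) + P1 * log(P1))
  }, maximize = FALSE)
}

# brute-force per-pixel neighborhood median (interior pixels only)
oracleMedian3 <- function(img) {
  H <- nrow(img); W <- ncol(img)
  out <- img
  for (y in 2:(H - 1)) for (x in 2:(W - 1))
    out[y, x] <- stats::median(img[(y - 1):(y + 1), (x - 1):(x + 1)])
  out
}

# rasterized disc mask (pixel-center test), used across feature tests
discMask <- function(r, pad = 5) {
  n <- 2 * (r + pad) + 1
  c0 <- r + pad
  xs <- matrix(rep(0:(n - 1), each = n), n)
  ys <- matrix(rep(0:(n - 1), n), n)
  (xs - c0)^2 + (ys - c0)^2 <= r^2
}

# rotated rectangle mask (pixel-center test), angle in degrees (y up)
barMask <- function(halfLen, halfWid, angleDeg, n = 2 * (halfLen + 10) + 1) {
  c0 <- (n - 1) / 2
  xs <- matrix(rep(0:(n - 1), each = n), n)
  ys <- matrix(rep(0:(n - 1), n), n)
  th <- angleDeg * pi / 180
  dx <- xs - c0; dyu <- -(ys - c0)
  u <- dx * cos(th) + dyu * sin(th)
  v <- -dx * sin(th) + dyu * cos(th)
  abs(u) <= halfLen & abs(v) <= halfWid
}

# small default-ish sequence shared by tracking/timeseries tests
smallSequence <- function(days = 2, imagesPerHour = 3, noiseSd = 0,
                          jump = TRUE, seed = 11) {
  plan <- experimentPlan(days = days, imagesPerHour = imagesPerHour)
  org <- organModel(initialSemiaxes = c(16, 11), growthRate = c(0.12, 0.1),
                    nutationAmplitude = 3, nutationPeriod = 24,
                    baseAngle = 25, center = c(80, 60))
  il <- illuminationModel(noiseSd = noiseSd, jumpEmulation = jump)
  simulateSequence(org, il, plan, seed = seed, size = c(120, 160))
}
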