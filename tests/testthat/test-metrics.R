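test_that("FSC has its defining symmetries", {
  v <- randomFourierVolume(16, 2, seed = 31)
  w <- randomFourierVolume(16, 2, seed = 32)
  self <- shellValues(fsc(v, v))
  expect_equal(self, rep(1, 9), tolerance = 1e-12)
  neg <- shellValues(fsc(v, fourierVolume(-v@data, 2)))
  expect_equal(neg, rep(-1, 9), tolerance = 1e-12)
  expect_identical(shellValues(fsc(v, w)), shellValues(fsc(w, v)))
  scaled <- fourierVolume(3.7 * w@data, 2)
  expect_equal(shellValues(fsc(v, scaled)), shellValues(fsc(v, w)),
               tolerance = 1e-12)
})

test_that("independent noise volumes decorrelate", {
  a <- randomFourierVolume(32, 2, seed = 33)
  b <- randomFourierVolume(32, 2, seed = 34)
  vals <- shellValues(fsc(a, b))
  ## shells with >= 100 voxels: skip the innermost few
  expect_true(all(abs(vals[5:17]) < 0.2))
})

test_that("masking both volumes preserves perfect correlation", {
  v <- randomRealVolume(32, 2, seed = 35)
  m <- softMask(32, 2, radius = 20, edgeWidth = 8)
  vm <- applyMask(v, m)
  expect_equal(shellValues(fsc(vm, vm)), rep(1, 17), tolerance = 1e-12)
})

test_that("resolutionAt interpolates threshold crossings", {
  ## constant 1: holds to Nyquist
  expect_equal(resolutionAt(rep(1, 17), 0.143, 2), 4)
  ## step profile: crossing between the bracketing shells, exactly
  ns <- 17; n <- 32; vox <- 2
  step <- c(rep(1, 6), rep(0, ns - 6))  # 1 through shell 5, 0 from shell 6
  r <- resolutionAt(step, 0.5, vox)
  expect_equal(r, n * vox / 5.5)
  ## below threshold already at shell 1: worst representable, flagged
  low <- c(1, rep(0.01, ns - 1))
  rlow <- resolutionAt(low, 0.143, vox)
  expect_equal(as.numeric(rlow), n * vox)
  expect_true(isTRUE(attr(rlow, "belowAtFirstShell")))
  ## random monotone profile equals the scan + interpolation oracle
  set.seed(36)
  prof <- sort(runif(ns, -0.2, 1), decreasing = TRUE)
  thr <- 0.3
  got <- resolutionAt(prof, thr, vox)
  scan <- which(prof < thr)[1]
  if (!is.na(scan) && scan > 1) {
    s0 <- scan - 2; f0 <- prof[scan - 1]; f1 <- prof[scan]
    cross <- s0 + (f0 - thr) / (f0 - f1)
    expect_equal(as.numeric(got), max(2 * vox, n * vox / cross))
  }
  ## monotone: pointwise-larger FSC never yields worse resolution
  prof2 <- pmin(1, prof + 0.1)
  expect_lte(resolutionAt(prof2, thr, vox), resolutionAt(prof, thr, vox))
})

test_that("soft masks have the raised-cosine edge profile", {
  n <- 64; vox <- 1
  radius <- 20; edge <- 8
  m <- softMask(n, vox, radius, edge)
  expect_true(all(m@data >= 0 & m@data <= 1))
  ## binary sphere when the edge collapses
  mb <- softMask(n, vox, radius, 0)
  expect_true(all(mb@data %in% c(0, 1)))
  ## exact half-way value at radius + edge/2 (probe on the x axis)
  centre <- n / 2 + 1
  probe <- m@data[centre + radius + edge / 2, centre, centre]
  expect_equal(probe, 0.5, tolerance = 1e-12)
  ## mask volume close to the analytic sphere + shell integral
  rr <- seq(radius, radius + edge, length.out = 2001)
  shellInt <- 4 * pi * stats::integrate(function(r)
    r^2 * 0.5 * (1 + cos(pi * (r - radius) / edge)),
    radius, radius + edge)$value
  analytic <- 4 / 3 * pi * radius^3 + shellInt
  expect_equal(sum(m@data), analytic, tolerance = 0.02)
  expect_error(softMask(32, 1, radius = 20, edgeWidth = 5), "exceeds")
})

test_that("angular errors agree with the quaternion oracle", {
  expect_equal(rotationAngle(diag(3), diag(3)), 0)
  flip <- diag(c(1, -1, -1))  # rotation by pi about x
  expect_equal(rotationAngle(diag(3), flip), pi, tolerance = 1e-12)
  set.seed(37)
  true <- lapply(1:20, function(i) quaternionToMatrix(rnorm(4)))
  est <- lapply(1:20, function(i) quaternionToMatrix(rnorm(4)))
  ae <- angularError(true, est)
  expect_true(all(ae$perImageError >= 0 & ae$perImageError <= pi))
  oracle <- mapply(function(a, b) {
    qa <- matrixToQuaternion(a); qb <- matrixToQuaternion(b)
    2 * acos(pmin(1, abs(sum(qa * qb))))
  }, true, est)
  expect_equal(ae$perImageError, oracle, tolerance = 1e-9)
  expect_equal(sum(ae$histogram$counts), 20)
})
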