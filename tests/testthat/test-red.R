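test_that("standardized denoising honours its contract", {
  v <- randomRealVolume(16, 2, seed = 21)
  idd <- identityDenoiser()
  expect_identical(standardizedDenoise(idd, v)@data, v@data)
  ## all-zero denoiser output reverses to a constant at the input mean
  zero <- denoiserHandle("zero", function(a) a * 0)
  out <- standardizedDenoise(zero, v)
  expect_equal(out@data, array(mean(v@data), dim(v@data)), tolerance = 1e-12)
  ## affine equivariance for any fixed denoiser
  cl <- classicalDenoiser(1.5)
  a <- 2.7; b <- -0.9
  lhs <- standardizedDenoise(cl, realVolume(a * v@data + b, 2))
  rhs <- a * standardizedDenoise(cl, v)@data + b
  expect_equal(lhs@data, rhs, tolerance = 1e-9)
  ## degenerate input
  expect_error(standardizedDenoise(idd, realVolume(array(1, c(16, 16, 16)),
                                                   2)), "zero-variance")
})

test_that("redGradient reproduces fixed points and linear shrinkage", {
  v <- randomRealVolume(16, 2, seed = 22)
  expect_true(all(redGradient(v, identityDenoiser(), 0.5)@data == 0))
  cshr <- 0.6
  shr <- denoiserHandle("shrink", function(a) cshr * a)
  g <- redGradient(v, shr, 2)
  vc <- v@data - mean(v@data)
  expect_equal(g@data, (cshr - 1) * vc / 2, tolerance = 1e-9)
})

test_that("redGradient matches the analytic Gaussian score (Tweedie)", {
  set.seed(23)
  n <- 24
  r2 <- 1.5^2
  u <- 0.7^2  # noise variance of the denoising problem
  x <- array(rnorm(n^3, sd = sqrt(r2)) + rnorm(n^3, sd = sqrt(u)),
             c(n, n, n))
  x <- x - mean(x)  # centre so the standardization wrapper is exact
  xv <- realVolume(x, 2)
  cshr <- r2 / (r2 + u)  # closed-form MMSE shrinkage
  mmse <- denoiserHandle("mmse", function(a) cshr * a)
  g <- redGradient(xv, mmse, u)
  analytic <- -x / (r2 + u)
  expect_lt(max(abs(g@data - analytic)), 1e-6 * max(abs(analytic)))
})

test_that("mstepRed reduces to the Gaussian update in its limits", {
  acc <- randomAccumulator(16, 2, seed = 24)
  ns <- 9
  set.seed(25)
  tau2 <- shellProfile(runif(ns, 0.5, 2), "tau2")
  d <- classicalDenoiser(1)
  ## lambda = 0: bit-exact Gaussian M-step
  expect_identical(mstepRed(acc, tau2, d, 0)@data,
                   mstepGaussian(acc, tau2)@data)
  ## tau^-2 = 0: the unregularized map, denoiser ignored
  free <- mstepRed(acc, shellProfile(rep(Inf, ns), "tau2"), d, 1)
  expect_equal(free@data, acc@B / acc@K, tolerance = 1e-12)
  ## lambda = 1 with the identity denoiser: direct per-voxel algebra
  x1 <- mstepRed(acc, tau2, identityDenoiser(), 1)
  xt <- acc@B / acc@K
  n <- 16
  tinvVals <- 1 / shellValues(tau2)
  k <- seq_len(n) - 1 - n / 2
  sGrid <- round(sqrt(outer(outer(k^2, k^2, `+`), k^2, `+`)))
  tinv <- array(tinvVals[pmin(sGrid, n / 2) + 1], dim(xt))
  expected <- (acc@B + tinv * xt) / (acc@K + tinv)
  expect_equal(x1@data, expected, tolerance = 1e-9)
  ## Hermitian symmetry survives the real-space denoiser round trip
  x2 <- mstepRed(acc, tau2, classicalDenoiser(2), 0.7)
  expect_lt(hermitianError(x2), 1e-6)
})

test_that("the confidence schedule interpolates between its boundaries", {
  sch <- lambdaSchedule()
  expect_identical(lambdaAt(sch, 12), 0)
  expect_identical(lambdaAt(sch, 4.0), 1)
  expect_equal(lambdaAt(sch, 7.25), 0.5)
  res <- seq(20, 3, by = -0.25)
  lam <- lambdaAt(sch, res)
  expect_true(all(diff(lam) >= 0))  # monotone as quality improves
  expect_equal(lambdaAt(sch, sch@resZero), 0)
  expect_equal(lambdaAt(sch, sch@resOne), 1)
  expect_error(lambdaSchedule(4, 10))
})

test_that("single-pass assessment averages ratios within bins", {
  gt <- makePhantom(phantomSpec(side = 16, voxelSize = 3, seed = 26))
  set.seed(27)
  pairs <- lapply(1:9, function(i) {
    noisy <- realVolume(gt@data + array(rnorm(16^3, sd = 0.3), dim(gt@data)),
                        3)
    list(input = noisy, groundTruth = gt,
         nominalResolution = 10 + i)
  })
  idr <- singlePassAssessment(pairs, identityDenoiser(), p = 2)
  rid <- attr(idr, "ratios")$ratio
  expect_equal(rid, rep(1, 9), tolerance = 1e-12)
  ## an oracle returning exactly the ground truth gives ratio 0
  oracleGt <- lapply(pairs, function(p) {
    d <- denoiserHandle("o", local({
      gtd <- p$groundTruth@data
      inp <- p$input@data
      function(a) (gtd - mean(inp)) / sd(as.vector(inp))
    }))
    attr(singlePassAssessment(list(p), d), "ratios")$ratio
  })
  expect_true(all(abs(unlist(oracleGt)) < 1e-9))
  ## binned means equal the brute-force group-by average
  br <- seq(10.5, 19.5, length.out = 4)
  res <- singlePassAssessment(pairs, classicalDenoiser(1), p = 1,
                              breaks = br)
  raw <- attr(res, "ratios")
  grp <- findInterval(raw$nominalResolution, br, rightmost.closed = TRUE,
                      all.inside = TRUE)
  for (b in unique(grp))
    expect_equal(res$meanRatio[b], mean(raw$ratio[grp == b]),
                 tolerance = 1e-12)
  ## a pair with zero unregularized error is skipped with a warning
  degen <- list(list(input = gt, groundTruth = gt, nominalResolution = 12))
  expect_warning(out <- singlePassAssessment(c(pairs, degen),
                                             identityDenoiser()),
                 "zero")
  expect_equal(attr(out, "skipped"), 1L)
})

test_that("CW-RED with the closed-form denoiser acts as a Wiener filter", {
  ## Gaussian toy: per-voxel observation xt = B/K with noise variance 1/K
  ## and prior variance tau2.  With the matching MMSE shrinkage denoiser
  ## and lambda = 1 the update is the closed-form combination
  ## (K + tau^-2 c)/(K + tau^-2) and approaches the analytic posterior-
  ## mean (Wiener) filter t/(t+1), t = K tau2, with O(1/t) discrepancy.
  runToy <- function(Kconst, tau2v = 1, n = 16) {
    truth <- randomRealVolume(n, 2, seed = 29)
    set.seed(28)
    noise <- array(rnorm(n^3, sd = sqrt(1 / Kconst)), c(n, n, n))
    xt <- forwardTransform(realVolume(truth@data + noise, 2))
    K <- array(Kconst, c(n, n, n))
    acc <- new("AccumulatorPair", B = xt@data * K, K = K, voxelSize = 2)
    cshr <- tau2v / (tau2v + 1 / Kconst)
    mmse <- denoiserHandle("mmse", function(a) cshr * a)
    upd <- mstepRed(acc, shellProfile(rep(tau2v, 9), "tau2"), mmse, 1)
    ## the standardization wrapper passes the DC term through unfiltered;
    ## compare on all other populated coefficients
    sel <- Mod(xt@data) > 1e-3
    sel[n / 2 + 1, n / 2 + 1, n / 2 + 1] <- FALSE
    tinv <- 1 / tau2v
    list(ratio = Mod(upd@data[sel] / xt@data[sel]),
         predicted = (Kconst + tinv * cshr) / (Kconst + tinv),
         wiener = Kconst * tau2v / (Kconst * tau2v + 1))
  }
  ## exact closed-form combination at any SNR
  toy <- runToy(Kconst = 50)
  expect_lt(max(abs(toy$ratio - toy$predicted)), 1e-9)
  expect_lt(max(abs(toy$ratio - toy$wiener)), 2 / 51)
  ## high-SNR shells: matches the posterior-mean filter within 1e-3
  hi <- runToy(Kconst = 5000)
  expect_lt(max(abs(hi$ratio - hi$wiener)), 1e-3)
})
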