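test_that("the shrinkage operator matches its closed form", {
  expect_equal(shrink(3, 2), 2)        # sgn(3) * (3 - min(1, 3))
  expect_equal(shrink(-0.3, 2), 0)     # min(1, 0.3) annihilates
  expect_equal(shrink(-3, 2), -2)
  z <- seq(-5, 5, by = 0.25)
  expect_equal(shrink(z, 0), z)        # zero threshold is the identity
  expect_error(shrink(1, -1), "b")
})

test_that("shrinkage is non-expansive, never grows magnitude, never flips sign", {
  z <- withr::with_seed(4, rnorm(500, sd = 2))
  for (b in c(0.1, 1, 3)) {
    g <- shrink(z, b)
    expect_true(all(abs(g) <= abs(z) + 1e-15))
    expect_true(all(g * z >= 0))
    z2 <- withr::with_seed(5, rnorm(500, sd = 2))
    expect_true(all(abs(shrink(z, b) - shrink(z2, b)) <= abs(z - z2) + 1e-12))
  }
})

test_that("the cost function reduces to known values in limiting cases", {
  acq <- fixtureAcquisition(64, accel = 5, sigma = 0.01, seed = 2)
  tmpl <- dwtForward(acq$x, "db2", 4L)
  zero <- setCoefficients(tmpl, rep(0, 64 * 64))
  expect_equal(costFunction(zero, acq$y, lambda = 1),
               sum(Mod(kspaceValues(acq$y))^2))
  # noiseless fully sampled data with the exact coefficients: zero misfit
  full <- makeMask(c(64, 64), 1)
  y0 <- forwardModel(acq$x, full, noiseSigma = 0)
  expect_lt(costFunction(tmpl, y0, lambda = 0),
            1e-10 * sum(Mod(kspaceValues(y0))^2))
})

test_that("the cost function is convex along random segments", {
  acq <- fixtureAcquisition(64, accel = 5, sigma = 0.01, seed = 3)
  tmpl <- dwtForward(acq$x, "db2", 4L)
  n <- 64 * 64
  for (seed in 1:5) {
    v1 <- withr::with_seed(seed, rnorm(n, sd = 50))
    v2 <- withr::with_seed(seed + 100, rnorm(n, sd = 50))
    sMid <- costFunction(setCoefficients(tmpl, (v1 + v2) / 2), acq$y, 0.5)
    s1 <- costFunction(setCoefficients(tmpl, v1), acq$y, 0.5)
    s2 <- costFunction(setCoefficients(tmpl, v2), acq$y, 0.5)
    expect_lte(sMid, (s1 + s2) / 2 + 1e-8 * abs(s1 + s2))
  }
})

test_that("one ISTA iteration matches the algebraic unrolling of the update", {
  acq <- fixtureAcquisition(64, accel = 5, sigma = 0.01, seed = 4)
  lam <- 5
  cfg <- solverConfig(lambda = lam, J = 2, maxIter = 1L, wavelet = "db2",
                      levels = 4L, seed = 1)
  res <- suppressWarnings(istaSolve(acq$y, cfg))
  # unroll by hand: omega0 = a; omega1 = shrink(a + (2/J)(a - A a), 2 lam / J)
  a <- flattenCoefficients(dwtForward(Re(applyUAdjoint(kspaceValues(acq$y),
                                                       acq$mask)), "db2", 4L))
  tmpl <- dwtForward(acq$x, "db2", 4L)
  Aa <- flattenCoefficients(dwtForward(
    Re(applyUAdjoint(applyU(dwtInverse(setCoefficients(tmpl, a)), acq$mask),
                     acq$mask)), "db2", 4L))
  omega1 <- shrink(a + (2 / 2) * (a - Aa), 2 * lam / 2)
  expect_equal(estimate(res), dwtInverse(setCoefficients(tmpl, omega1)),
               tolerance = 1e-12)
})

test_that("ISTA recovers the image under full sampling with negligible regularization", {
  x <- fixturePhantom(64)
  full <- makeMask(c(64, 64), 1)
  y <- forwardModel(x, full, noiseSigma = 0)
  res <- istaSolve(y, solverConfig(lambda = 1e-6, maxIter = 100L,
                                   wavelet = "db2", levels = 4L))
  relErr <- sqrt(sum((estimate(res) - x)^2) / sum(x^2))
  expect_lt(relErr, 1e-3)
})

test_that("the ISTA cost trace is non-increasing when the step bound holds", {
  acq <- fixtureAcquisition(64, accel = 5, sigma = 0.01, seed = 6)
  res <- suppressWarnings(
    istaSolve(acq$y, solverConfig(J = 2, maxIter = 40L, wavelet = "db2",
                                  levels = 4L, seed = 1), acq$x))
  ct <- costTrace(res)
  expect_length(ct, 40L)
  expect_true(all(diff(ct) <= 1e-9 * abs(ct[-length(ct)])))
  expect_length(psnrTrace(res), 40L)
})

test_that("ISTA solves the orthonormal-Q lasso in closed form", {
  # full sampling + orthonormal wavelet => Q unitary => the minimizer is the
  # soft-thresholded back-projection at threshold lambda/2
  x <- fixturePhantom(64)
  full <- makeMask(c(64, 64), 1)
  y <- forwardModel(x, full, noiseSigma = 0.5, seed = 9)
  lam <- 8
  res <- suppressWarnings(
    istaSolve(y, solverConfig(lambda = lam, J = 2, maxIter = 50L,
                              wavelet = "db2", levels = 4L)))
  a <- flattenCoefficients(dwtForward(Re(applyUAdjoint(kspaceValues(y), full)),
                                      "db2", 4L))
  oracle <- sign(a) * pmax(abs(a) - lam / 2, 0)   # independent closed form
  tmpl <- dwtForward(x, "db2", 4L)
  expect_lt(max(abs(estimate(res) -
                    dwtInverse(setCoefficients(tmpl, oracle)))), 1e-8)
})

test_that("FISTA reaches a cost no worse than ISTA at the same budget", {
  acq <- fixtureAcquisition(64, accel = 5, sigma = 0.01, seed = 8)
  ci <- solverConfig(maxIter = 50L, wavelet = "db2", levels = 4L, seed = 1)
  ri <- istaSolve(acq$y, ci)
  rf <- fistaSolve(acq$y, ci)
  expect_lte(tail(costTrace(rf), 1), tail(costTrace(ri), 1) * (1 + 1e-9))
  expect_identical(rf@solver, "fista")
})

test_that("the linear baselines reject nonlinear/shifted configurations", {
  acq <- fixtureAcquisition(64, seed = 2)
  expect_error(istaSolve(acq$y, solverConfig(ewtK = 3L)), "ewtK")
  expect_error(fistaSolve(acq$y, solverConfig(shiftEnabled = TRUE)), "ewtK")
  expect_error(ewistarsSolve(acq$y, solverConfig(ewtK = 0L)), "ewtK")
})

test_that("a step constant violating the bound triggers a warning but proceeds", {
  acq <- fixtureAcquisition(64, seed = 2)
  expect_warning(
    istaSolve(acq$y, solverConfig(J = 0.5, maxIter = 2L, wavelet = "db2",
                                  levels = 4L)),
    "step bound")
})

test_that("EWISTARS is bit-reproducible and leaves its inputs unmodified", {
  acq <- fixtureAcquisition(64, accel = 5, sigma = 0.01, seed = 5)
  yBefore <- kspaceValues(acq$y)
  maskBefore <- keepMatrix(acq$mask)
  cfg <- solverConfig(maxIter = 15L, ewtK = 3L, wavelet = "db2", levels = 4L,
                      shiftEnabled = TRUE, seed = 42)
  r1 <- ewistarsSolve(acq$y, cfg, acq$x)
  r2 <- ewistarsSolve(acq$y, cfg, acq$x)
  expect_identical(estimate(r1), estimate(r2))
  expect_identical(costTrace(r1), costTrace(r2))
  expect_identical(shiftLog(r1), shiftLog(r2))
  expect_identical(kspaceValues(acq$y), yBefore)
  expect_identical(keepMatrix(acq$mask), maskBefore)
  # a fresh shift is drawn every iteration
  expect_equal(nrow(shiftLog(r1)), 15L)
  expect_gt(nrow(unique(shiftLog(r1))), 5)
})

test_that("EWISTARS recovers the image in the consistency limit", {
  x <- fixturePhantom(64)
  full <- makeMask(c(64, 64), 1)
  y <- forwardModel(x, full, noiseSigma = 0)
  res <- ewistarsSolve(y, solverConfig(lambda = 1e-9, maxIter = 20L,
                                       ewtK = 2L, wavelet = "db2",
                                       levels = 4L, shiftEnabled = FALSE))
  relErr <- sqrt(sum((estimate(res) - x)^2) / sum(x^2))
  expect_lt(relErr, 1e-2)
})

test_that("early stopping on the relative-change tolerance truncates the traces", {
  x <- fixturePhantom(64)
  full <- makeMask(c(64, 64), 1)
  y <- forwardModel(x, full, noiseSigma = 0)
  res <- ewistarsSolve(y, solverConfig(lambda = 1e-9, maxIter = 50L,
                                       ewtK = 1L, wavelet = "db1",
                                       levels = 3L, shiftEnabled = FALSE,
                                       tol = 1e-6))
  expect_lt(iterationsRun(res), 50L)
  expect_length(costTrace(res), iterationsRun(res))
  expect_equal(nrow(shiftLog(res)), iterationsRun(res))
})
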