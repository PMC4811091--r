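test_that("joint normalization maps the global extrema to 0 and 1 and inverts exactly", {
  base <- dwtForward(randomImage(32, seed = 1), "db2", 2L)
  v <- flattenCoefficients(base)
  v[1] <- -3
  v[2] <- 5
  v[-(1:2)] <- pmin(pmax(v[-(1:2)] / 100, -3), 5)
  wc <- setCoefficients(base, v)
  nz <- normalize01(wc)
  nv <- flattenCoefficients(nz$coeffs)
  expect_equal(min(nv), 0)
  expect_equal(max(nv), 1)
  expect_equal(nz$range, c(-3, 5))
  expect_equal(flattenCoefficients(denormalize01(nz$coeffs, nz$range)), v,
               tolerance = 1e-12)
})

test_that("constant coefficient sets normalize to zero with a unit-range guard", {
  base <- dwtForward(matrix(0, 32, 32), "db1", 2L)
  wc <- setCoefficients(base, rep(4.2, 32 * 32))
  nz <- normalize01(wc)
  expect_true(all(flattenCoefficients(nz$coeffs) == 0))
  expect_equal(nz$range, c(4.2, 4.2))
  expect_equal(flattenCoefficients(denormalize01(nz$coeffs, nz$range)),
               rep(4.2, 32 * 32))
  bad <- setCoefficients(base, c(NaN, rep(0, 32 * 32 - 1)))
  expect_error(normalize01(bad), "non-finite")
})

test_that("the exponential map fixes the endpoints and evaluates (e^0.5-1)/(e-1) at 0.5", {
  # craft an image whose db1 coefficients are exactly {0, 1, 0.5, 0, ...}
  base <- dwtForward(matrix(0, 32, 32), "db1", 2L)
  v <- rep(0, 32 * 32)
  v[2] <- 1
  v[3] <- 0.5
  x <- dwtInverse(setCoefficients(base, v))
  st <- ewtForward(x, k = 1, wavelet = "db1", levels = 2L)
  w <- flattenCoefficients(st)
  expect_equal(min(w), 0)          # 0 stays 0
  expect_equal(max(w), 1)          # 1 stays 1
  expect_equal(w[3], (exp(0.5) - 1) / (exp(1) - 1), tolerance = 1e-10)
  expect_equal(w[3], 0.3775406687981455, tolerance = 1e-12)
})

test_that("the exponential map preserves coefficient ranks", {
  x <- fixturePhantom(64)
  dv <- flattenCoefficients(dwtForward(x, "bior4.4", 3L))
  ev <- flattenCoefficients(ewtForward(x, k = 1, wavelet = "bior4.4",
                                       levels = 3L))
  expect_equal(cor(dv, ev, method = "spearman"), 1)
})

test_that("EWT round trips are exact for k up to 10 and degrade smoothly", {
  x <- randomImage(64, seed = 12)
  errs <- vapply(1:10, function(k) {
    st <- ewtForward(x, k, wavelet = "db2", levels = 3L)
    max(abs(ewtInverse(st) - x))
  }, numeric(1))
  expect_true(all(errs <= 1e-6))
  expect_lt(max(errs) / max(1e-14, min(errs)), 1e6)  # no catastrophic blowup
})

test_that("one exponential step does not decrease coefficient sparsity (Gini)", {
  for (seed in c(7, 8, 9)) {
    x <- makePhantom(64, "piecewise_texture", seed = seed)
    wc <- dwtForward(x, "bior4.4", 3L)
    u <- flattenCoefficients(normalize01(wc)$coeffs)
    w <- flattenCoefficients(ewtForward(x, 1, "bior4.4", 3L))
    expect_gte(giniIndex(w), giniIndex(u))
  }
})

test_that("thresholded EWT states invert to finite images", {
  x <- fixturePhantom(64)
  st <- ewtForward(x, 3, "bior4.4", 3L)
  v <- shrink(flattenCoefficients(st), 0.2)
  out <- ewtInverse(setCoefficients(st, v))
  expect_true(all(is.finite(out)))
})

test_that("the EWT image of wavelet-zero inverts to the zero image", {
  x <- fixturePhantom(64)
  st <- ewtForward(x, 4, "db3", 3L)
  z0 <- ewtZeroPoint(st)
  expect_gt(z0, 0)
  expect_lt(z0, 1)
  flat <- setCoefficients(st, rep(z0, length(flattenCoefficients(st))))
  expect_lt(max(abs(ewtInverse(flat))), 1e-8)
})

test_that("invalid exponent counts are rejected", {
  x <- fixturePhantom(64)
  expect_error(ewtForward(x, 0, "db1", 2L), "k")
})
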