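smallGrid <- function(...) {
  experimentGrid(solvers = "ista", wavelets = "db2", kValues = 1,
                 accelerations = 5, seeds = 1,
                 phantom = list(size = 64, kind = "piecewise_texture",
                                textureAmplitude = 20, seed = 7),
                 levels = 4L, noiseSigma = 0.01, maxIter = 10L, ...)
}

test_that("a one-cell grid yields one internally consistent row", {
  tab <- runComparison(smallGrid())
  expect_equal(nrow(tab), 1L)
  expect_named(tab, c("solver", "wavelet", "levels", "k", "acceleration",
                      "noise_sigma", "seed", "mae", "mse", "psnr",
                      "iterations"))
  expect_equal(tab$psnr, psnrFromMse(tab$mse), tolerance = 1e-12)
  expect_lte(tab$mae, sqrt(tab$mse))
  expect_equal(tab$iterations, 10L)
})

test_that("experiment tables are byte-identical across reruns", {
  g <- experimentGrid(solvers = c("ista", "ewistars"), wavelets = "db2",
                      kValues = 2, accelerations = 5, seeds = c(1, 2),
                      phantom = list(size = 64, kind = "piecewise_texture",
                                     textureAmplitude = 20, seed = 7),
                      levels = 4L, noiseSigma = 0.01, maxIter = 5L)
  expect_identical(runComparison(g), runComparison(g))
})

test_that("grid validity guards against explosion and empty axes", {
  expect_error(smallGrid(cap = 0L), "cap")
  expect_error(experimentGrid(solvers = character(0)), "non-empty")
})

test_that("the k sweep returns one finite PSNR per k and flags the argmax", {
  ks <- runKSweep(kValues = c(1, 2, 3),
                  phantom = list(size = 64, kind = "piecewise_texture",
                                 textureAmplitude = 20, seed = 7),
                  levels = 4L, maxIter = 10L, seed = 1)
  expect_equal(ks$k, c(1, 2, 3))
  expect_true(all(is.finite(ks$psnr)))
  expect_true(attr(ks, "argmax_k") %in% ks$k)
  expect_equal(ks$psnr[which(ks$k == attr(ks, "argmax_k"))], max(ks$psnr))
})

test_that("the wavelet sweep covers the requested wavelets and rejects unknown ones", {
  ws <- runWaveletSweep(wavelets = c("db1", "bior2.2"),
                        phantom = list(size = 64, kind = "piecewise_texture",
                                       textureAmplitude = 20, seed = 7),
                        levels = 4L, maxIter = 10L, seed = 1, k = 2L)
  expect_equal(nrow(ws), 2L)
  expect_equal(ws$wavelet, c("db1", "bior2.2"))
  expect_true(all(is.finite(ws$psnr)))
  expect_error(runWaveletSweep(wavelets = "sym4"), "unknown")
})

test_that("reconstruction results persist and restore with full provenance", {
  acq <- fixtureAcquisition(64, seed = 3)
  res <- ewistarsSolve(acq$y, solverConfig(maxIter = 5L, ewtK = 2L,
                                           wavelet = "db2", levels = 4L,
                                           shiftEnabled = TRUE, seed = 1),
                       acq$x)
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveReconResult(res, f, y = acq$y, groundTruth = acq$x)
  back <- loadReconResult(f)
  expect_identical(back$estimate, estimate(res))
  expect_identical(back$ground_truth, acq$x)
  expect_identical(back$trace$cost, costTrace(res))
  expect_s4_class(back$config, "SolverConfig")
  # provenance is complete: rerunning with the stored inputs reproduces the
  # estimate bit for bit
  rerun <- ewistarsSolve(forwardModel(back$ground_truth, back$mask,
                                      noiseSigma = acq$y@noiseSigma,
                                      seed = acq$y@seed),
                         back$config, back$ground_truth)
  expect_identical(estimate(rerun), back$estimate)
})
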