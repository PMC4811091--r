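# Experiment drivers: solver comparison grids, exponent (k) sweeps and
# wavelet sweeps on synthetic phantoms, mirroring the standard CS-MRI study
# designs (undersample, add noise, reconstruct, score).

#' Construct an experiment grid
#'
#' @param solvers subset of \code{c("ista", "fista", "ewistars")}.
#' @param wavelets wavelet names, see [supportedWavelets()].
#' @param kValues exponential iteration counts used by EWISTARS cells
#'   (ignored by the linear baselines).
#' @param accelerations undersampling factors.
#' @param seeds integer seeds; each seed drives the mask, the noise and the
#'   solver of its cell.
#' @param phantom list with elements \code{size}, \code{kind},
#'   \code{textureAmplitude}, \code{seed}, passed to [makePhantom()].
#' @param levels wavelet decomposition depth.
#' @param noiseSigma k-space noise standard deviation.
#' @param maxIter iteration budget per cell.
#' @param cap maximum number of cells (guard against accidental explosion).
#' @return an [ExperimentGrid-class].
#' @export
experimentGrid <- function(solvers = c("ista", "fista", "ewistars"),
                           wavelets = "bior4.4",
                           kValues = 6,
                           accelerations = 5,
                           seeds = 1,
                           phantom = list(size = 128, kind = "piecewise_texture",
                                          textureAmplitude = 20, seed = 7),
                           levels = 5L, noiseSigma = 0.01, maxIter = 100L,
                           cap = 500L) {
  new("ExperimentGrid", solvers = solvers, wavelets = wavelets,
      kValues = as.numeric(kValues), accelerations = as.numeric(accelerations),
      seeds = as.numeric(seeds), phantom = phantom, levels = as.integer(levels),
      noiseSigma = as.numeric(noiseSigma), maxIter = as.integer(maxIter),
      cap = as.integer(cap))
}

phantomFromSpec <- function(p) {
  makePhantom(p$size,
              kind = if (is.null(p$kind)) "piecewise_texture" else p$kind,
              textureAmplitude = if (is.null(p$textureAmplitude)) 20 else p$textureAmplitude,
              seed = if (is.null(p$seed)) 0L else p$seed)
}

runCell <- function(x, solver, wavelet, levels, k, accel, noiseSigma, maxIter,
                    seed, lambda = NA_real_, withTruth = TRUE) {
  mask <- makeMask(dim(x), accel, "variable_density_random", seed = seed)
  y <- forwardModel(x, mask, noiseSigma = noiseSigma, seed = seed + 1L)
  cfg <- switch(solver,
    ista = solverConfig(lambda = lambda, maxIter = maxIter, ewtK = 0L,
                        wavelet = wavelet, levels = levels, seed = seed + 2L),
    fista = solverConfig(lambda = lambda, maxIter = maxIter, ewtK = 0L,
                         wavelet = wavelet, levels = levels, seed = seed + 2L),
    ewistars = solverConfig(lambda = lambda, maxIter = maxIter,
                            ewtK = as.integer(k), wavelet = wavelet,
                            levels = levels, shiftEnabled = TRUE,
                            seed = seed + 2L),
    stop("unknown solver '", solver, "'", call. = FALSE))
  fn <- switch(solver, ista = istaSolve, fista = fistaSolve,
               ewistars = ewistarsSolve)
  fn(y, cfg, groundTruth = if (withTruth) x else NULL)
}

#' Run a solver-comparison experiment
#'
#' Evaluates every cell of the grid (solver x wavelet x k x acceleration x
#' seed) on the grid's phantom: simulate the undersampled noisy acquisition,
#' reconstruct, and score MAE/MSE/PSNR against the ground truth. Failed cells
#' are reported with \code{NA} metrics and a message; the rest continue. The
#' result is a pure function of the grid (seeds included).
#'
#' @param grid an [ExperimentGrid-class].
#' @return data.frame with one row per cell: solver, wavelet, levels, k,
#'   acceleration, noise_sigma, seed, mae, mse, psnr, iterations.
#' @export
runComparison <- function(grid) {
  x <- phantomFromSpec(grid@phantom)
  cells <- expand.grid(solver = grid@solvers, wavelet = grid@wavelets,
                       k = grid@kValues, acceleration = grid@accelerations,
                       seed = grid@seeds, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    ci <- cells[i, ]
    out <- data.frame(solver = ci$solver, wavelet = ci$wavelet,
                      levels = grid@levels, k = ci$k,
                      acceleration = ci$acceleration,
                      noise_sigma = grid@noiseSigma, seed = ci$seed,
                      mae = NA_real_, mse = NA_real_, psnr = NA_real_,
                      iterations = NA_integer_)
    res <- tryCatch(
      runCell(x, ci$solver, ci$wavelet, grid@levels, ci$k, ci$acceleration,
              grid@noiseSigma, grid@maxIter, as.integer(ci$seed)),
      error = function(e) {
        message(sprintf("cell %d (%s/%s) failed: %s", i, ci$solver,
                        ci$wavelet, conditionMessage(e)))
        NULL
      })
    if (!is.null(res)) {
      rep <- metricReport(x, estimate(res))
      out$mae <- rep@mae
      out$mse <- rep@mse
      out$psnr <- rep@psnr
      out$iterations <- iterationsRun(res)
    }
    out
  })
  do.call(rbind, rows)
}

#' Sweep the exponential iteration count k
#'
#' Runs EWISTARS for each value of \code{k} on a fixed-seed phantom and
#' records the final PSNR. The returned data.frame carries the argmax k as
#' attribute \code{"argmax_k"}. Lambda is held fixed across arms (the
#' adaptive default resolves to the same value for every k, since the EWT
#' coefficient maximum is pinned at 1).
#'
#' @param kValues integer vector of exponent counts.
#' @param phantom phantom specification list (see [experimentGrid()]).
#' @param acceleration,noiseSigma acquisition settings.
#' @param wavelet,levels transform settings.
#' @param maxIter iteration budget.
#' @param seed integer seed shared by all arms.
#' @param lambda fixed lambda (NA = adaptive, identical across arms).
#' @return data.frame with columns \code{k} and \code{psnr}.
#' @export
runKSweep <- function(kValues = 1:10,
                      phantom = list(size = 128, kind = "piecewise_texture",
                                     textureAmplitude = 20, seed = 7),
                      acceleration = 5, noiseSigma = 0.01,
                      wavelet = "bior4.4", levels = 5L, maxIter = 100L,
                      seed = 1L, lambda = NA_real_) {
  stopifnot(length(kValues) >= 1)
  x <- phantomFromSpec(phantom)
  ps <- vapply(kValues, function(k) {
    res <- runCell(x, "ewistars", wavelet, levels, k, acceleration,
                   noiseSigma, maxIter, as.integer(seed), lambda = lambda)
    psnr(x, estimate(res))
  }, numeric(1))
  out <- data.frame(k = kValues, psnr = ps)
  attr(out, "argmax_k") <- kValues[which.max(ps)]
  out
}

#' Sweep the sparsifying wavelet
#'
#' Runs EWISTARS once per wavelet on a fixed-seed phantom and reports the
#' final PSNR per wavelet.
#'
#' @param wavelets wavelet names.
#' @inheritParams runKSweep
#' @param k exponential iteration count.
#' @return data.frame with columns \code{wavelet} and \code{psnr}.
#' @export
runWaveletSweep <- function(wavelets = supportedWavelets(),
                            phantom = list(size = 128, kind = "piecewise_texture",
                                           textureAmplitude = 20, seed = 7),
                            acceleration = 5, noiseSigma = 0.01, k = 6L,
                            levels = 5L, maxIter = 100L, seed = 1L,
                            lambda = NA_real_) {
  bad <- setdiff(wavelets, supportedWavelets())
  if (length(bad)) stop("unknown wavelet(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  x <- phantomFromSpec(phantom)
  ps <- vapply(wavelets, function(w) {
    res <- runCell(x, "ewistars", w, levels, k, acceleration, noiseSigma,
                   maxIter, as.integer(seed), lambda = lambda)
    psnr(x, estimate(res))
  }, numeric(1))
  data.frame(wavelet = wavelets, psnr = unname(ps))
}

#' Persist / restore a reconstruction result
#'
#' Stores the reconstruction with its provenance (ground truth if given,
#' mask, measured k-space, estimate, traces, configuration) as a single
#' serialized container keyed by those names.
#'
#' @param result a [ReconResult-class].
#' @param path output file.
#' @param y optional [KSpaceData-class] to store alongside.
#' @param groundTruth optional reference image to store alongside.
#' @return invisibly, the path.
#' @export
saveReconResult <- function(result, path, y = NULL, groundTruth = NULL) {
  obj <- list(ground_truth = groundTruth,
              mask = if (is.null(y)) NULL else y@mask,
              y = if (is.null(y)) NULL else kspaceValues(y),
              estimate = estimate(result),
              trace = list(cost = costTrace(result), psnr = psnrTrace(result)),
              config = solverConfigOf(result),
              result = result)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveReconResult
#' @export
loadReconResult <- function(path) readRDS(path)
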