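#' @import methods
NULL

#' k-space sampling mask
#'
#' Boolean inclusion pattern over a DC-centered k-space grid. The stored
#' \code{keep} matrix uses the convention that the zero-frequency (DC) sample
#' sits at row \code{floor(H/2)+1}, column \code{floor(W/2)+1}; the Fourier
#' operators shift at their boundary. The fraction of kept samples is within
#' 10\% of \code{1/acceleration}, and the DC sample is always kept.
#'
#' @slot keep logical matrix, \code{TRUE} where k-space is measured.
#' @slot acceleration numeric undersampling factor (>= 1); factor 5 means
#'   roughly 20\% of k-space is acquired.
#' @slot scheme character; one of \code{"variable_density_random"},
#'   \code{"radial_lines"}, \code{"uniform_random"}.
#' @slot seed integer seed the mask was drawn with.
#'
#' @seealso [makeMask()]
#' @export
setClass("SamplingMask",
  representation(keep = "matrix", acceleration = "numeric",
                 scheme = "character", seed = "integer"))

setValidity("SamplingMask", function(object) {
  k <- object@keep
  if (!is.logical(k)) return("'keep' must be a logical matrix")
  if (nrow(k) %% 2L != 0L || ncol(k) %% 2L != 0L)
    return("mask dimensions must be even")
  if (length(object@acceleration) != 1L || object@acceleration < 1)
    return("'acceleration' must be a single value >= 1")
  dc <- c(floor(nrow(k) / 2) + 1L, floor(ncol(k) / 2) + 1L)
  if (!k[dc[1L], dc[2L]]) return("DC sample must be kept")
  frac <- mean(k)
  target <- 1 / object@acceleration
  if (abs(frac - target) > 0.1 * target)
    return(sprintf("kept fraction %.4f not within 10%% of 1/acceleration = %.4f",
                   frac, target))
  TRUE
})

#' Measured k-space data
#'
#' Complex undersampled Fourier measurements \eqn{y = U x + e}: the unitary
#' 2-D DFT of an image restricted to a sampling mask, with optional complex
#' white Gaussian noise on the measured points. Values are stored DC-centered
#' and are exactly zero off the mask.
#'
#' @slot values complex matrix of measurements (zero where not sampled).
#' @slot mask a [SamplingMask-class].
#' @slot noiseSigma numeric, noise standard deviation per real/imaginary
#'   component on kept samples.
#' @slot seed integer noise seed.
#'
#' @seealso [forwardModel()]
#' @export
setClass("KSpaceData",
  representation(values = "matrix", mask = "SamplingMask",
                 noiseSigma = "numeric", seed = "integer"))

setValidity("KSpaceData", function(object) {
  if (!is.complex(object@values)) return("'values' must be complex")
  if (!identical(dim(object@values), dim(object@mask@keep)))
    return("values/mask dimension mismatch")
  if (any(object@values[!object@mask@keep] != 0))
    return("values must be exactly zero off the mask")
  if (object@noiseSigma < 0) return("'noiseSigma' must be >= 0")
  TRUE
})

#' Multilevel 2-D wavelet coefficient set
#'
#' Output of the periodized separable multilevel discrete wavelet transform:
#' one approximation band at the coarsest level plus three detail bands
#' (horizontal/vertical/diagonal) per level. \code{details[[j]]} holds the
#' bands of level \code{j}, with level 1 the finest.
#'
#' @slot approx numeric matrix, coarsest approximation band.
#' @slot details list of per-level lists with elements \code{lh}, \code{hl},
#'   \code{hh}.
#' @slot wavelet character wavelet name (\code{"db1"} ... \code{"bior4.4"}).
#' @slot levels integer decomposition depth.
#' @slot dim integer(2), size of the image the transform was taken of.
#'
#' @seealso [dwtForward()], [dwtInverse()], [flattenCoefficients()]
#' @export
setClass("WaveletCoefficients",
  representation(approx = "matrix", details = "list",
                 wavelet = "character", levels = "integer", dim = "integer"))

setValidity("WaveletCoefficients", function(object) {
  if (length(object@details) != object@levels)
    return("'details' must have one entry per level")
  n <- prod(dim(object@approx)) +
    sum(vapply(object@details,
               function(l) sum(vapply(l, length, integer(1))), numeric(1)))
  if (n != prod(object@dim))
    return("total coefficient count inconsistent with image size")
  TRUE
})

#' Exponential wavelet transform state
#'
#' Wavelet coefficients after \code{k} rounds of joint [0,1] normalization
#' followed by the exponential map \eqn{v \mapsto (e^v - 1)/(e - 1)}, plus
#' the per-round \code{(c_min, c_max)} pairs needed to invert exactly.
#'
#' @slot coeffs a [WaveletCoefficients-class] holding the transformed values.
#' @slot k integer number of exponential iterations (>= 1).
#' @slot normParams list of length \code{k}; each element \code{c(c_min, c_max)}
#'   recorded before the corresponding normalization.
#'
#' @seealso [ewtForward()], [ewtInverse()]
#' @export
setClass("EWTState",
  representation(coeffs = "WaveletCoefficients", k = "integer",
                 normParams = "list"))

setValidity("EWTState", function(object) {
  if (object@k < 1L) return("'k' must be >= 1")
  if (length(object@normParams) != object@k)
    return("need exactly k (c_min, c_max) pairs")
  ok <- vapply(object@normParams,
               function(p) is.numeric(p) && length(p) == 2L && p[2L] >= p[1L],
               logical(1))
  if (!all(ok)) return("each normParams entry must be c(c_min, c_max) with c_max >= c_min")
  TRUE
})

#' Solver configuration
#'
#' Parameters shared by the ISTA, FISTA and EWISTARS reconstruction loops.
#' \code{lambda} trades data fidelity against sparsity; when \code{NA} it is
#' chosen adaptively as 0.01 times the largest coefficient magnitude in the
#' domain being thresholded at initialization. \code{J} is the step/majorizer
#' constant, required to satisfy \eqn{J \ge 2\lambda_{max}(Q^H Q)}; when
#' \code{NA} it defaults to 2 for orthonormal wavelets and to a 5\%-padded
#' power-iteration estimate for biorthogonal ones.
#'
#' @slot lambda numeric regularization weight (\code{NA} = adaptive).
#' @slot J numeric step constant (\code{NA} = automatic).
#' @slot maxIter integer maximum number of iterations.
#' @slot ewtK integer number of exponential iterations (0 = plain wavelet).
#' @slot wavelet character wavelet name.
#' @slot levels integer decomposition depth.
#' @slot shiftEnabled logical; draw a fresh random circular shift each
#'   iteration (EWISTARS only).
#' @slot seed integer seed for all solver randomness.
#' @slot tol numeric early-stop threshold on the relative change of the
#'   estimate (0 disables).
#'
#' @seealso [solverConfig()], [ewistarsSolve()]
#' @export
setClass("SolverConfig",
  representation(lambda = "numeric", J = "numeric", maxIter = "integer",
                 ewtK = "integer", wavelet = "character", levels = "integer",
                 shiftEnabled = "logical", seed = "integer", tol = "numeric"))

setValidity("SolverConfig", function(object) {
  if (!is.na(object@lambda) && object@lambda <= 0)
    return("'lambda' must be > 0 (or NA for adaptive)")
  if (!is.na(object@J) && object@J <= 0) return("'J' must be > 0 (or NA)")
  if (object@maxIter < 1L) return("'maxIter' must be >= 1")
  if (object@ewtK < 0L) return("'ewtK' must be >= 0")
  if (object@tol < 0) return("'tol' must be >= 0")
  if (!object@wavelet %in% supportedWavelets())
    return(sprintf("unknown wavelet '%s'", object@wavelet))
  TRUE
})

#' Reconstruction result
#'
#' Image estimate with per-iteration cost and PSNR traces, the random-shift
#' log, and the full configuration (including the resolved lambda and J), so
#' that a run can be reproduced bit-for-bit.
#'
#' @slot estimate numeric matrix, the reconstructed image (not clipped).
#' @slot costTrace numeric, the l1-regularized least-squares cost per
#'   iteration, evaluated on the linear wavelet coefficients of the estimate
#'   so that curves are comparable across solvers.
#' @slot psnrTrace numeric, PSNR versus ground truth per iteration (length 0
#'   when no ground truth was supplied).
#' @slot iterationsRun integer number of iterations actually run.
#' @slot config the [SolverConfig-class] used.
#' @slot shiftLog integer matrix with one \code{(s_row, s_col)} row per
#'   iteration (zero rows when shifting is disabled).
#' @slot lambdaUsed,jUsed numeric, the resolved values of lambda and J.
#' @slot solver character, one of \code{"ista"}, \code{"fista"},
#'   \code{"ewistars"}.
#'
#' @export
setClass("ReconResult",
  representation(estimate = "matrix", costTrace = "numeric",
                 psnrTrace = "numeric", iterationsRun = "integer",
                 config = "SolverConfig", shiftLog = "matrix",
                 lambdaUsed = "numeric", jUsed = "numeric",
                 solver = "character"))

setValidity("ReconResult", function(object) {
  n <- object@iterationsRun
  if (length(object@costTrace) != n) return("costTrace length must equal iterationsRun")
  if (!length(object@psnrTrace) %in% c(0L, n))
    return("psnrTrace must be empty or of length iterationsRun")
  if (nrow(object@shiftLog) != n) return("shiftLog must have one row per iteration")
  TRUE
})

#' Reconstruction quality report
#'
#' MAE, MSE and PSNR between a reconstruction and its ground truth, computed
#' on images clipped to the 8-bit display range [0, 255] (PSNR uses peak 255).
#'
#' @slot mae,mse numeric mean absolute / squared error.
#' @slot psnr numeric peak signal-to-noise ratio in dB (\code{Inf} for
#'   identical images).
#' @slot nPixels integer number of pixels compared.
#'
#' @seealso [metricReport()]
#' @export
setClass("MetricReport",
  representation(mae = "numeric", mse = "numeric", psnr = "numeric",
                 nPixels = "integer"))

setValidity("MetricReport", function(object) {
  if (object@mae < 0 || object@mse < 0) return("errors must be non-negative")
  if (object@mae > sqrt(object@mse) + 1e-9)
    return("MAE must not exceed sqrt(MSE)")
  if (object@mse > 0) {
    expect <- 20 * log10(255 / sqrt(object@mse))
    if (abs(object@psnr - expect) > 1e-9 * max(1, abs(expect)))
      return("PSNR inconsistent with MSE")
  }
  TRUE
})

#' Experiment grid
#'
#' Cartesian product of solvers, wavelets, exponent values, acceleration
#' factors and seeds, evaluated on a common synthetic phantom. The product is
#' capped to guard against accidental explosion.
#'
#' @slot solvers,wavelets character vectors.
#' @slot kValues,accelerations,seeds numeric vectors.
#' @slot phantom list with elements \code{size}, \code{kind},
#'   \code{textureAmplitude}, \code{seed} (see [makePhantom()]).
#' @slot levels integer wavelet decomposition depth.
#' @slot noiseSigma numeric k-space noise level.
#' @slot maxIter integer iteration budget per cell.
#' @slot cap integer maximum number of grid cells.
#'
#' @seealso [experimentGrid()], [runComparison()]
#' @export
setClass("ExperimentGrid",
  representation(solvers = "character", wavelets = "character",
                 kValues = "numeric", accelerations = "numeric",
                 seeds = "numeric", phantom = "list", levels = "integer",
                 noiseSigma = "numeric", maxIter = "integer", cap = "integer"))

setValidity("ExperimentGrid", function(object) {
  axes <- list(object@solvers, object@wavelets, object@kValues,
               object@accelerations, object@seeds)
  if (any(vapply(axes, length, integer(1)) == 0L))
    return("all grid axes must be non-empty")
  n <- prod(vapply(axes, length, integer(1)))
  if (n > object@cap)
    return(sprintf("grid has %d cells, exceeding cap %d", n, object@cap))
  TRUE
})
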