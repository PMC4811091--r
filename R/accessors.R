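#' @rdname SamplingMask-class
#' @export
setMethod("keepMatrix", "SamplingMask", function(object) object@keep)

#' @rdname SamplingMask-class
#' @export
setMethod("acceleration", "SamplingMask", function(object) object@acceleration)

#' @rdname SamplingMask-class
#' @export
setMethod("samplingScheme", "SamplingMask", function(object) object@scheme)

#' @rdname KSpaceData-class
#' @export
setMethod("kspaceValues", "KSpaceData", function(object) object@values)

#' @rdname KSpaceData-class
#' @export
setMethod("noiseSigma", "KSpaceData", function(object) object@noiseSigma)

#' @rdname WaveletCoefficients-class
#' @export
setMethod("waveletName", "WaveletCoefficients", function(object) object@wavelet)

#' @rdname WaveletCoefficients-class
#' @export
setMethod("waveletLevels", "WaveletCoefficients", function(object) object@levels)

#' @rdname flattenCoefficients
#' @export
setMethod("flattenCoefficients", "WaveletCoefficients", function(object) {
  c(as.vector(object@approx),
    unlist(lapply(rev(seq_len(object@levels)), function(j) {
      l <- object@details[[j]]
      c(as.vector(l$lh), as.vector(l$hl), as.vector(l$hh))
    }), use.names = FALSE))
})

#' @rdname setCoefficients
#' @export
setMethod("setCoefficients", "WaveletCoefficients", function(object, values) {
  stopifnot(length(values) == prod(object@dim))
  pos <- 0L
  take <- function(d) {
    n <- prod(d)
    m <- matrix(values[(pos + 1L):(pos + n)], d[1L], d[2L])
    pos <<- pos + n
    m
  }
  object@approx <- take(dim(object@approx))
  for (j in rev(seq_len(object@levels))) {
    for (b in c("lh", "hl", "hh"))
      object@details[[j]][[b]] <- take(dim(object@details[[j]][[b]]))
  }
  object
})

#' @rdname flattenCoefficients
#' @export
setMethod("flattenCoefficients", "EWTState",
          function(object) flattenCoefficients(object@coeffs))

#' @rdname setCoefficients
#' @export
setMethod("setCoefficients", "EWTState", function(object, values) {
  object@coeffs <- setCoefficients(object@coeffs, values)
  object
})

#' @rdname ReconResult-class
#' @export
setMethod("estimate", "ReconResult", function(object) object@estimate)

#' @rdname ReconResult-class
#' @export
setMethod("costTrace", "ReconResult", function(object) object@costTrace)

#' @rdname ReconResult-class
#' @export
setMethod("psnrTrace", "ReconResult", function(object) object@psnrTrace)

#' @rdname ReconResult-class
#' @export
setMethod("iterationsRun", "ReconResult", function(object) object@iterationsRun)

#' @rdname ReconResult-class
#' @export
setMethod("shiftLog", "ReconResult", function(object) object@shiftLog)

#' @rdname ReconResult-class
#' @export
setMethod("solverConfigOf", "ReconResult", function(object) object@config)

setMethod("show", "SamplingMask", function(object) {
  cat(sprintf("SamplingMask %dx%d, scheme '%s', acceleration %.2f (kept %.1f%%), seed %d\n",
              nrow(object@keep), ncol(object@keep), object@scheme,
              object@acceleration, 100 * mean(object@keep), object@seed))
})

setMethod("show", "KSpaceData", function(object) {
  cat(sprintf("KSpaceData %dx%d, %d measured samples, noise sigma %g, seed %d\n",
              nrow(object@values), ncol(object@values),
              sum(object@mask@keep), object@noiseSigma, object@seed))
})

setMethod("show", "WaveletCoefficients", function(object) {
  cat(sprintf("WaveletCoefficients: %s, %d levels, image %dx%d (%d coefficients)\n",
              object@wavelet, object@levels, object@dim[1L], object@dim[2L],
              prod(object@dim)))
})

setMethod("show", "EWTState", function(object) {
  rng <- range(flattenCoefficients(object))
  cat(sprintf("EWTState: %s, %d levels, k = %d, coefficient range [%.3g, %.3g]\n",
              object@coeffs@wavelet, object@coeffs@levels, object@k,
              rng[1L], rng[2L]))
})

setMethod("show", "SolverConfig", function(object) {
  cat(sprintf(
    "SolverConfig: wavelet %s x%d levels, k = %d, lambda = %s, J = %s,\n  maxIter = %d, shift %s, tol = %g, seed = %d\n",
    object@wavelet, object@levels, object@ewtK,
    if (is.na(object@lambda)) "auto" else format(object@lambda),
    if (is.na(object@J)) "auto" else format(object@J),
    object@maxIter, if (object@shiftEnabled) "on" else "off",
    object@tol, object@seed))
})

setMethod("show", "ReconResult", function(object) {
  cat(sprintf("ReconResult (%s): %dx%d estimate, %d iterations, final cost %.4g",
              object@solver, nrow(object@estimate), ncol(object@estimate),
              object@iterationsRun,
              object@costTrace[length(object@costTrace)]))
  if (length(object@psnrTrace))
    cat(sprintf(", final PSNR %.2f dB", object@psnrTrace[length(object@psnrTrace)]))
  cat("\n")
})

setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport: MAE %.4g, MSE %.4g, PSNR %.2f dB over %d pixels\n",
              object@mae, object@mse, object@psnr, object@nPixels))
})

setMethod("show", "ExperimentGrid", function(object) {
  n <- length(object@solvers) * length(object@wavelets) *
    length(object@kValues) * length(object@accelerations) *
    length(object@seeds)
  cat(sprintf("ExperimentGrid: %d cells (%d solvers x %d wavelets x %d k x %d accel x %d seeds)\n",
              n, length(object@solvers), length(object@wavelets),
              length(object@kValues), length(object@accelerations),
              length(object@seeds)))
})
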