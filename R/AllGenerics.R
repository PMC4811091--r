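#' @rdname SamplingMask-class
#' @param object,x an object.
#' @export
setGeneric("keepMatrix", function(object) standardGeneric("keepMatrix"))

#' @rdname SamplingMask-class
#' @export
setGeneric("acceleration", function(object) standardGeneric("acceleration"))

#' @rdname SamplingMask-class
#' @export
setGeneric("samplingScheme", function(object) standardGeneric("samplingScheme"))

#' @rdname KSpaceData-class
#' @param object an object.
#' @export
setGeneric("kspaceValues", function(object) standardGeneric("kspaceValues"))

#' @rdname KSpaceData-class
#' @export
setGeneric("noiseSigma", function(object) standardGeneric("noiseSigma"))

#' @rdname WaveletCoefficients-class
#' @param object an object.
#' @export
setGeneric("waveletName", function(object) standardGeneric("waveletName"))

#' @rdname WaveletCoefficients-class
#' @export
setGeneric("waveletLevels", function(object) standardGeneric("waveletLevels"))

#' Flatten a coefficient set to a numeric vector
#'
#' The layout is fixed (approximation band first, then per-level detail bands
#' from coarsest to finest, each in column-major order) so that
#' \code{setCoefficients(object, flattenCoefficients(object))} is an exact
#' round trip.
#'
#' @param object a [WaveletCoefficients-class] or [EWTState-class].
#' @return numeric vector of all coefficients.
#' @export
setGeneric("flattenCoefficients",
           function(object) standardGeneric("flattenCoefficients"))

#' Replace all coefficient values from a flat vector
#'
#' @param object a [WaveletCoefficients-class] or [EWTState-class].
#' @param values numeric vector as produced by [flattenCoefficients()].
#' @return the object with the same layout and new values.
#' @export
setGeneric("setCoefficients",
           function(object, values) standardGeneric("setCoefficients"))

#' @rdname ReconResult-class
#' @param object an object.
#' @export
setGeneric("estimate", function(object) standardGeneric("estimate"))

#' @rdname ReconResult-class
#' @export
setGeneric("costTrace", function(object) standardGeneric("costTrace"))

#' @rdname ReconResult-class
#' @export
setGeneric("psnrTrace", function(object) standardGeneric("psnrTrace"))

#' @rdname ReconResult-class
#' @export
setGeneric("iterationsRun", function(object) standardGeneric("iterationsRun"))

#' @rdname ReconResult-class
#' @export
setGeneric("shiftLog", function(object) standardGeneric("shiftLog"))

#' @rdname ReconResult-class
#' @export
setGeneric("solverConfigOf", function(object) standardGeneric("solverConfigOf"))
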