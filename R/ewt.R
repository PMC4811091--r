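# Exponential wavelet transform: iterated [0,1] normalization followed by
# the convex map v -> (e^v - 1)/(e - 1) on the wavelet coefficients. The map
# fixes 0 and 1, is strictly increasing, and is convex, so large (normalized)
# coefficients are enhanced relative to small ones - the sparsity-boosting
# mechanism the reconstruction exploits.

expMap <- function(v) (exp(v) - 1) / (exp(1) - 1)
logMap <- function(v) log1p((exp(1) - 1) * v)

#' Jointly normalize wavelet coefficients to [0, 1]
#'
#' Applies the affine map \eqn{v \mapsto (v - c_{min})/(c_{max} - c_{min})}
#' using the global extrema over all bands jointly (preserving inter-band
#' magnitude ordering) and returns the recorded \code{(c_min, c_max)} pair
#' needed to invert. A constant input maps to all zeros with the range guard
#' \code{c_max - c_min := 1}.
#'
#' @param coeffs a [WaveletCoefficients-class] with finite values.
#' @return list with elements \code{coeffs} (normalized) and \code{range}
#'   (\code{c(c_min, c_max)}).
#' @seealso [denormalize01()]
#' @export
normalize01 <- function(coeffs) {
  v <- flattenCoefficients(coeffs)
  if (!all(is.finite(v))) stop("non-finite coefficients", call. = FALSE)
  cmin <- min(v)
  cmax <- max(v)
  span <- if (cmax > cmin) cmax - cmin else 1
  list(coeffs = setCoefficients(coeffs, (v - cmin) / span),
       range = c(cmin, cmax))
}

#' Invert the [0, 1] normalization
#'
#' @param coeffs normalized [WaveletCoefficients-class].
#' @param range the \code{c(c_min, c_max)} pair recorded by [normalize01()].
#' @return the denormalized coefficient set.
#' @export
denormalize01 <- function(coeffs, range) {
  span <- if (range[2L] > range[1L]) range[2L] - range[1L] else 1
  setCoefficients(coeffs, flattenCoefficients(coeffs) * span + range[1L])
}

#' Exponential wavelet transform
#'
#' Computes the wavelet decomposition once, then applies \code{k} rounds of
#' \{normalize jointly to [0, 1], recording \code{(c_min, c_max)}; apply
#' \eqn{v \mapsto (e^v - 1)/(e - 1)}\}. Output coefficients therefore lie in
#' [0, 1]. The recorded per-round ranges make [ewtInverse()] an exact inverse.
#'
#' @param x numeric image matrix.
#' @param k number of exponential iterations (>= 1).
#' @param wavelet,levels wavelet specification, as in [dwtForward()].
#' @return an [EWTState-class].
#' @examples
#' x <- makePhantom(64, "shepp_logan")
#' s <- ewtForward(x, k = 3, wavelet = "db2", levels = 3)
#' max(abs(ewtInverse(s) - x)) < 1e-6
#' @export
ewtForward <- function(x, k, wavelet = "bior4.4", levels = 5L) {
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be >= 1", call. = FALSE)
  wc <- dwtForward(x, wavelet, levels)
  params <- vector("list", k)
  for (i in seq_len(k)) {
    nz <- normalize01(wc)
    params[[i]] <- nz$range
    wc <- setCoefficients(nz$coeffs, expMap(flattenCoefficients(nz$coeffs)))
  }
  new("EWTState", coeffs = wc, k = k, normParams = params)
}

#' EWT image of a zero wavelet coefficient
#'
#' Tracks the value 0 through the state's recorded normalization rounds and
#' exponential maps. Because the [0, 1] normalization is affine (not purely
#' a scaling), a wavelet coefficient of exactly 0 does not map to 0 in the
#' EWT domain but to this point; it is the natural rest point toward which
#' shrinkage must pull EWT coefficients for thresholding to suppress (rather
#' than corrupt) small wavelet coefficients.
#'
#' @param state an [EWTState-class].
#' @return scalar, the EWT-domain coordinate of wavelet-zero.
#' @export
ewtZeroPoint <- function(state) {
  z <- 0
  for (p in state@normParams) {
    span <- if (p[2L] > p[1L]) p[2L] - p[1L] else 1
    z <- expMap((z - p[1L]) / span)
  }
  z
}

#' Invert the exponential wavelet transform
#'
#' Applies, for each of the \code{k} rounds in reverse order, \{clip to
#' [0, 1]; \eqn{v \mapsto \ln(1 + (e - 1) v)}; denormalize with the stored
#' \code{(c_min, c_max)}\}, then the inverse wavelet transform. The clip
#' makes the map well defined on soft-thresholded states, where tiny negative
#' values can arise from floating-point error; 0 itself is in the log map's
#' domain and maps to the recorded minimum.
#'
#' @param state an [EWTState-class].
#' @return numeric image matrix.
#' @export
ewtInverse <- function(state) {
  wc <- state@coeffs
  for (i in rev(seq_len(state@k))) {
    v <- flattenCoefficients(wc)
    v <- pmin(pmax(v, 0), 1)
    wc <- denormalize01(setCoefficients(wc, logMap(v)), state@normParams[[i]])
  }
  dwtInverse(wc)
}
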