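# Reconstruction-quality metrics. Both arguments are clipped to the 8-bit
# display range [0, 255] before comparison, since PSNR hard-codes peak 255;
# without clipping, transient solver overshoot would make PSNR incomparable
# across solvers.

#' Mean absolute error
#'
#' @param x,xStar numeric matrices of equal dimensions (clipped to [0, 255]
#'   before comparison when \code{clip = TRUE}).
#' @param clip clip both images to the display range first (default).
#' @return mean of \code{|x - xStar|} over all pixels.
#' @export
mae <- function(x, xStar, clip = TRUE) {
  assertSameDim(x, xStar)
  if (clip) { x <- clip255(x); xStar <- clip255(xStar) }
  mean(abs(x - xStar))
}

#' Mean squared error
#'
#' @inheritParams mae
#' @return mean of \code{(x - xStar)^2} over all pixels.
#' @export
mse <- function(x, xStar, clip = TRUE) {
  assertSameDim(x, xStar)
  if (clip) { x <- clip255(x); xStar <- clip255(xStar) }
  mean((x - xStar)^2)
}

#' Peak signal-to-noise ratio (dB)
#'
#' \eqn{PSNR = 20 \log_{10}(255/\sqrt{MSE})} with 8-bit peak 255; returns
#' \code{Inf} for identical images.
#'
#' @inheritParams mae
#' @return PSNR in decibels.
#' @examples
#' psnrFromMse(16.31)  # about 36.01 dB
#' @export
psnr <- function(x, xStar, clip = TRUE) {
  psnrFromMse(mse(x, xStar, clip = clip))
}

#' @rdname psnr
#' @param m a mean squared error value.
#' @export
psnrFromMse <- function(m) {
  if (m == 0) return(Inf)
  20 * log10(255 / sqrt(m))
}

#' Full metric report
#'
#' @inheritParams mae
#' @return a [MetricReport-class] with MAE, MSE and PSNR.
#' @export
metricReport <- function(x, xStar, clip = TRUE) {
  m <- mse(x, xStar, clip = clip)
  new("MetricReport", mae = mae(x, xStar, clip = clip), mse = m,
      psnr = psnrFromMse(m), nPixels = length(x))
}

#' Brightened absolute-error map
#'
#' \code{|x - xStar|} multiplied by \code{brighten} and clipped to [0, 255],
#' for visual inspection of where a reconstruction deviates.
#'
#' @inheritParams mae
#' @param brighten multiplicative factor (>= 1; default 5).
#' @return numeric matrix in [0, 255].
#' @export
errorMap <- function(x, xStar, brighten = 5) {
  assertSameDim(x, xStar)
  if (brighten < 1) stop("'brighten' must be >= 1", call. = FALSE)
  clip255(abs(x - xStar) * brighten)
}
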