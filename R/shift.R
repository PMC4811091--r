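# Random circular shifts (cycle spinning). The decimated wavelet transform
# is translation variant; shifting the image by a fresh random offset each
# iteration before the transform, and undoing it after, restores translation
# invariance in expectation and suppresses blocking artifacts.

#' Draw a uniform random circular shift
#'
#' Draws \code{s_row ~ U\{0..H-1\}}, \code{s_col ~ U\{0..W-1\}} from the
#' current RNG stream (callers seed the stream; the solvers do this via
#' their config seed).
#'
#' @param shape integer(2), image dimensions.
#' @return integer(2) shift vector.
#' @export
drawShift <- function(shape) {
  c(sample.int(shape[1L], 1L) - 1L, sample.int(shape[2L], 1L) - 1L)
}

#' Circularly shift / unshift an image
#'
#' \code{circShift} moves content down by \code{s[1]} rows and right by
#' \code{s[2]} columns with wrap-around; \code{circUnshift} is its exact
#' inverse for any shift.
#'
#' @param x numeric matrix.
#' @param s integer(2) shift vector.
#' @return shifted matrix.
#' @export
circShift <- function(x, s) {
  H <- nrow(x); W <- ncol(x)
  x[((seq_len(H) - 1L - s[1L]) %% H) + 1L,
    ((seq_len(W) - 1L - s[2L]) %% W) + 1L, drop = FALSE]
}

#' @rdname circShift
#' @export
circUnshift <- function(x, s) circShift(x, -s)
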