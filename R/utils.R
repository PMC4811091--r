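# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards so library calls never perturb user code.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

# DC-centering index permutation for an even length n: entry 1 (DC of the raw
# FFT layout) moves to position n/2 + 1. Self-inverse for even n.
shiftIndex <- function(n) c((floor(n / 2) + 1L):n, seq_len(floor(n / 2)))

fftshift2 <- function(x) x[shiftIndex(nrow(x)), shiftIndex(ncol(x)), drop = FALSE]
ifftshift2 <- fftshift2

# Unitary 2-D DFT and inverse (norm preserved, so operator norms are
# scale-free and the ISTA step bound is concrete).
unitaryFFT <- function(x) stats::fft(x) / sqrt(length(x))
unitaryIFFT <- function(x) stats::fft(x, inverse = TRUE) / sqrt(length(x))

assertSameDim <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("dimension mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), call. = FALSE)
  invisible(TRUE)
}

#' Gini index of a magnitude vector
#'
#' A scale-invariant sparsity measure in [0, 1): 0 for a uniform magnitude
#' profile, approaching 1 when energy concentrates in few entries. Used to
#' quantify how much the exponential map concentrates wavelet coefficients.
#'
#' @param x numeric vector (absolute values are taken).
#' @return the Gini index of \code{abs(x)}.
#' @examples
#' giniIndex(c(1, 0, 0, 0))  # sparse: close to 1
#' giniIndex(rep(1, 4))      # uniform: 0
#' @export
giniIndex <- function(x) {
  v <- sort(abs(as.vector(x)))
  n <- length(v)
  s <- sum(v)
  if (s == 0) return(0)
  (2 * sum(seq_len(n) * v)) / (n * s) - (n + 1) / n
}
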