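# Undersampled Fourier acquisition: y = U x + e, with U the unitary 2-D DFT
# restricted to a sampling mask (DC-centered indexing).

dcIndex <- function(dims) c(floor(dims[1L] / 2) + 1L, floor(dims[2L] / 2) + 1L)

maskVariableDensity <- function(dims, targetRows) {
  H <- dims[1L]
  dc <- floor(H / 2) + 1L
  d <- abs(seq_len(H) - dc)
  w <- exp(-d^2 / (2 * (H / 4)^2))    # Gaussian density, sigma = H/4
  p <- pmin(1, targetRows * w / sum(w))
  kept <- stats::runif(H) < p
  kept[dc] <- TRUE
  # adjust to the exact target count, preferring to drop low-density rows
  # and to add high-density rows
  over <- sum(kept) - targetRows
  if (over > 0) {
    cand <- setdiff(which(kept), dc)
    drop <- sample(cand, over, prob = 1 - w[cand] + 1e-9)
    kept[drop] <- FALSE
  } else if (over < 0) {
    cand <- which(!kept)
    add <- sample(cand, -over, prob = w[cand] + 1e-9)
    kept[add] <- TRUE
  }
  matrix(kept, dims[1L], dims[2L])
}

maskRadial <- function(dims, targetCount) {
  H <- dims[1L]; W <- dims[2L]
  dc <- dcIndex(dims)
  offset <- stats::runif(1, 0, pi)
  drawLines <- function(nLines) {
    keep <- matrix(FALSE, H, W)
    ang <- offset + pi * (seq_len(nLines) - 1) / nLines
    tmax <- sqrt(H^2 + W^2) / 2
    ts <- seq(-tmax, tmax, by = 0.5)
    for (a in ang) {
      rr <- round(dc[1L] + ts * sin(a))
      cc <- round(dc[2L] + ts * cos(a))
      ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
      keep[cbind(rr[ok], cc[ok])] <- TRUE
    }
    keep
  }
  nLines <- max(1L, round(targetCount / (0.75 * max(H, W))))
  for (i in 1:60) {
    keep <- drawLines(nLines)
    frac <- sum(keep) / targetCount
    if (frac > 1.08) nLines <- nLines - max(1L, round(nLines * 0.05))
    else if (frac < 0.92) nLines <- nLines + max(1L, round(nLines * 0.05))
    else break
  }
  keep[dc[1L], dc[2L]] <- TRUE
  keep
}

maskUniform <- function(dims, targetCount) {
  n <- prod(dims)
  dcLin <- (dcIndex(dims)[2L] - 1L) * dims[1L] + dcIndex(dims)[1L]
  pick <- sample.int(n, targetCount)
  if (!dcLin %in% pick) pick[1L] <- dcLin
  keep <- logical(n)
  keep[pick] <- TRUE
  matrix(keep, dims[1L], dims[2L])
}

#' Generate a k-space sampling mask
#'
#' Deterministic per seed. \code{"variable_density_random"} keeps full
#' phase-encode rows drawn with probability decaying from the k-space center
#' under a Gaussian density (sigma = H/4), then adds/removes rows to hit the
#' target count exactly — the standard CS-MRI Cartesian scheme.
#' \code{"radial_lines"} rasterizes equiangular spokes through the center
#' (count adjusted to the target sampling fraction); \code{"uniform_random"}
#' keeps an exact uniform sample of k-space points. The DC sample is always
#' kept, and \code{acceleration = 1} yields the fully sampled mask.
#'
#' @param shape integer(2) mask dimensions (must be even).
#' @param acceleration undersampling factor (> 1, or exactly 1 for full
#'   sampling); factor 5 keeps roughly 20\% of k-space.
#' @param scheme sampling scheme.
#' @param seed integer seed.
#' @return a [SamplingMask-class].
#' @examples
#' m <- makeMask(c(64, 64), 5, seed = 1)
#' mean(keepMatrix(m))  # about 0.2
#' @export
makeMask <- function(shape,
                     acceleration,
                     scheme = c("variable_density_random", "radial_lines",
                                "uniform_random"),
                     seed = 0L) {
  scheme <- match.arg(scheme)
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 4L) || any(shape %% 2L != 0L))
    stop("'shape' must be two even integers", call. = FALSE)
  if (acceleration < 1) stop("'acceleration' must be >= 1", call. = FALSE)
  if (acceleration >= shape[1L])
    stop("'acceleration' must be smaller than the number of rows", call. = FALSE)

  if (acceleration == 1) {
    keep <- matrix(TRUE, shape[1L], shape[2L])
  } else {
    keep <- withSeed(seed, switch(scheme,
      variable_density_random =
        maskVariableDensity(shape, max(1L, round(shape[1L] / acceleration))),
      radial_lines = maskRadial(shape, round(prod(shape) / acceleration)),
      uniform_random = maskUniform(shape, round(prod(shape) / acceleration))))
  }
  new("SamplingMask", keep = keep, acceleration = as.numeric(acceleration),
      scheme = scheme, seed = as.integer(seed))
}

#' Apply the undersampled Fourier operator U
#'
#' \code{applyU} computes the unitary 2-D DFT of an image, shifts it to the
#' DC-centered layout, and zeroes the unmeasured samples. \code{applyUAdjoint}
#' is its exact adjoint: mask, shift back, inverse unitary DFT (the
#' "zero-filled" reconstruction, complex-valued).
#'
#' @param x numeric (or complex) matrix with the mask's dimensions.
#' @param mask a [SamplingMask-class].
#' @return complex matrix (DC-centered masked spectrum for \code{applyU};
#'   image-domain array for \code{applyUAdjoint}).
#' @export
applyU <- function(x, mask) {
  assertSameDim(x, mask@keep)
  ks <- fftshift2(unitaryFFT(x))
  ks * mask@keep
}

#' @rdname applyU
#' @param yValues complex DC-centered k-space matrix.
#' @export
applyUAdjoint <- function(yValues, mask) {
  assertSameDim(yValues, mask@keep)
  unitaryIFFT(ifftshift2(yValues * mask@keep))
}

#' Simulate an undersampled, noisy MRI acquisition
#'
#' Computes \eqn{y = U x + e}: the masked unitary Fourier transform of the
#' image plus complex circular white Gaussian noise with standard deviation
#' \code{noiseSigma} per real/imaginary component, injected only on the
#' measured samples. Bit-reproducible for a fixed seed.
#'
#' @param x numeric image matrix.
#' @param mask a [SamplingMask-class].
#' @param noiseSigma noise standard deviation per component (>= 0).
#' @param seed integer noise seed.
#' @return a [KSpaceData-class].
#' @export
forwardModel <- function(x, mask, noiseSigma = 0, seed = 0L) {
  assertSameDim(x, mask@keep)
  if (noiseSigma < 0) stop("'noiseSigma' must be >= 0", call. = FALSE)
  y <- applyU(x, mask)
  if (noiseSigma > 0) {
    n <- length(y)
    e <- withSeed(seed, complex(real = stats::rnorm(n, sd = noiseSigma),
                                imaginary = stats::rnorm(n, sd = noiseSigma)))
    y <- y + matrix(e, nrow(y), ncol(y)) * mask@keep
  }
  new("KSpaceData", values = y, mask = mask,
      noiseSigma = as.numeric(noiseSigma), seed = as.integer(seed))
}

#' Estimate the spectral norm of a self-adjoint operator by power iteration
#'
#' Used to verify the ISTA step bound: with unitary FFT normalization
#' \eqn{U^H U} is an orthogonal projector conjugated by a unitary, so its
#' largest eigenvalue is exactly 1 for any non-empty mask.
#'
#' @param applyA function mapping a real vector/matrix to another of the same
#'   shape (must be self-adjoint positive semi-definite).
#' @param shape integer(2) operand shape.
#' @param iters number of power iterations.
#' @param seed seed for the random start vector.
#' @return the estimated largest eigenvalue.
#' @export
powerIteration <- function(applyA, shape, iters = 50L, seed = 0L) {
  v <- withSeed(seed, matrix(stats::rnorm(prod(shape)), shape[1L], shape[2L]))
  v <- v / sqrt(sum(v^2))
  lam <- 0
  for (i in seq_len(iters)) {
    w <- applyA(v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    lam <- sum(v * w)
    v <- w / nw
  }
  lam
}
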