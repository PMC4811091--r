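# Periodized separable multilevel 2-D discrete wavelet transform.
#
# Filter banks are the standard published Daubechies (db1-db3) and
# biorthogonal spline (bior2.2, bior3.3, bior4.4) coefficients. Boundary
# handling is periodic (circular), so circular image shifts commute exactly
# with the transform grid and coefficient counts equal pixel counts.
#
# Convention: analysis is circular convolution with the decomposition
# filters, downsampled at phase L-1 (L = filter length); synthesis upsamples
# and circularly convolves with the reconstruction filters at phase 0. This
# pairing gives perfect reconstruction for every supported filter bank.

waveletFilters <- local({
  banks <- list(
    db1 = list(
      dl = c(0.7071067811865476, 0.7071067811865476),
      dh = c(-0.7071067811865476, 0.7071067811865476),
      rl = c(0.7071067811865476, 0.7071067811865476),
      rh = c(0.7071067811865476, -0.7071067811865476)),
    db2 = list(
      dl = c(-0.12940952255126037, 0.2241438680420134, 0.8365163037378079,
             0.48296291314453416),
      dh = c(-0.48296291314453416, 0.8365163037378079, -0.2241438680420134,
             -0.12940952255126037),
      rl = c(0.48296291314453416, 0.8365163037378079, 0.2241438680420134,
             -0.12940952255126037),
      rh = c(-0.12940952255126037, -0.2241438680420134, 0.8365163037378079,
             -0.48296291314453416)),
    db3 = list(
      dl = c(0.03522629188570953, -0.08544127388202666, -0.13501102001025458,
             0.45987750211849154, 0.8068915093110925, 0.33267055295008263),
      dh = c(-0.33267055295008263, 0.8068915093110925, -0.45987750211849154,
             -0.13501102001025458, 0.08544127388202666, 0.03522629188570953),
      rl = c(0.33267055295008263, 0.8068915093110925, 0.45987750211849154,
             -0.13501102001025458, -0.08544127388202666, 0.03522629188570953),
      rh = c(0.03522629188570953, 0.08544127388202666, -0.13501102001025458,
             -0.45987750211849154, 0.8068915093110925, -0.33267055295008263)),
    "bior2.2" = list(
      dl = c(0, -0.1767766952966369, 0.3535533905932738, 1.0606601717798212,
             0.3535533905932738, -0.1767766952966369),
      dh = c(0, 0.3535533905932738, -0.7071067811865476, 0.3535533905932738,
             0, 0),
      rl = c(0, 0.3535533905932738, 0.7071067811865476, 0.3535533905932738,
             0, 0),
      rh = c(0, 0.1767766952966369, 0.3535533905932738, -1.0606601717798212,
             0.3535533905932738, 0.1767766952966369)),
    "bior3.3" = list(
      dl = c(0.06629126073623882, -0.1988737822087165, -0.15467960838455727,
             0.9943689110435825, 0.9943689110435825, -0.15467960838455727,
             -0.1988737822087165, 0.06629126073623882),
      dh = c(0, 0, -0.1767766952966369, 0.5303300858899106,
             -0.5303300858899106, 0.1767766952966369, 0, 0),
      rl = c(0, 0, 0.1767766952966369, 0.5303300858899106,
             0.5303300858899106, 0.1767766952966369, 0, 0),
      rh = c(0.06629126073623882, 0.1988737822087165, -0.15467960838455727,
             -0.9943689110435825, 0.9943689110435825, 0.15467960838455727,
             -0.1988737822087165, -0.06629126073623882)),
    "bior4.4" = list(
      dl = c(0, 0.03782845550726404, -0.023849465019556843,
             -0.11062440441843718, 0.37740285561283066, 0.8526986790088938,
             0.37740285561283066, -0.11062440441843718, -0.023849465019556843,
             0.03782845550726404),
      dh = c(0, -0.06453888262869706, 0.04068941760916406,
             0.41809227322161724, -0.7884856164055829, 0.41809227322161724,
             0.04068941760916406, -0.06453888262869706, 0, 0),
      rl = c(0, -0.06453888262869706, -0.04068941760916406,
             0.41809227322161724, 0.7884856164055829, 0.41809227322161724,
             -0.04068941760916406, -0.06453888262869706, 0, 0),
      rh = c(0, -0.03782845550726404, -0.023849465019556843,
             0.11062440441843718, 0.37740285561283066, -0.8526986790088938,
             0.37740285561283066, 0.11062440441843718, -0.023849465019556843,
             -0.03782845550726404)))
  function(name) {
    f <- banks[[name]]
    if (is.null(f)) stop("unknown wavelet '", name, "'", call. = FALSE)
    f
  }
})

#' Supported wavelet names
#'
#' @return character vector of the wavelet names accepted throughout the
#'   package.
#' @export
supportedWavelets <- function() {
  c("db1", "db2", "db3", "bior2.2", "bior3.3", "bior4.4")
}

# One analysis step along columns: X (N x M) -> list(a, d), each (N/2 x M).
dwtStepCols <- function(X, dl, dh) {
  N <- nrow(X)
  L <- length(dl)
  k <- seq.int(0L, N / 2 - 1L)
  A <- matrix(0, N / 2, ncol(X))
  D <- A
  for (m in 0:(L - 1L)) {
    rows <- ((2L * k - m + (L - 1L)) %% N) + 1L
    Xm <- X[rows, , drop = FALSE]
    A <- A + dl[m + 1L] * Xm
    D <- D + dh[m + 1L] * Xm
  }
  list(a = A, d = D)
}

idwtStepCols <- function(A, D, rl, rh) {
  N <- 2L * nrow(A)
  L <- length(rl)
  k <- seq.int(0L, N / 2 - 1L)
  X <- matrix(0, N, ncol(A))
  for (m in 0:(L - 1L)) {
    rows <- ((2L * k + m) %% N) + 1L
    X[rows, ] <- X[rows, , drop = FALSE] + rl[m + 1L] * A + rh[m + 1L] * D
  }
  X
}

checkLevels <- function(dims, levels) {
  maxLev <- floor(log2(min(dims))) - 2L
  if (levels < 1L || levels > maxLev)
    stop(sprintf("'levels' must be in 1..%d for a %dx%d image",
                 maxLev, dims[1L], dims[2L]), call. = FALSE)
  if (any(dims %% 2L^levels != 0L))
    stop("image dimensions must be divisible by 2^levels", call. = FALSE)
}

#' Multilevel 2-D discrete wavelet transform
#'
#' Separable periodized decomposition: each level splits the current
#' approximation into an approximation band plus horizontal (\code{lh}),
#' vertical (\code{hl}) and diagonal (\code{hh}) detail bands.
#' \code{dwtInverse} is the exact inverse up to floating-point error.
#'
#' @param x numeric image matrix (dimensions divisible by \code{2^levels}).
#' @param wavelet wavelet name, see [supportedWavelets()].
#' @param levels decomposition depth; must satisfy
#'   \code{levels <= log2(min(dim(x))) - 2}.
#' @return a [WaveletCoefficients-class].
#' @examples
#' x <- makePhantom(64, "shepp_logan")
#' w <- dwtForward(x, "db1", 3)
#' max(abs(dwtInverse(w) - x)) < 1e-8
#' @export
dwtForward <- function(x, wavelet = "bior4.4", levels = 5L) {
  levels <- as.integer(levels)
  checkLevels(dim(x), levels)
  f <- waveletFilters(wavelet)
  details <- vector("list", levels)
  cur <- x
  for (j in seq_len(levels)) {
    colStep <- dwtStepCols(cur, f$dl, f$dh)
    lo <- dwtStepCols(t(colStep$a), f$dl, f$dh)   # rows of the low band
    hi <- dwtStepCols(t(colStep$d), f$dl, f$dh)
    cur <- t(lo$a)
    details[[j]] <- list(lh = t(lo$d), hl = t(hi$a), hh = t(hi$d))
  }
  new("WaveletCoefficients", approx = cur, details = details,
      wavelet = wavelet, levels = levels, dim = as.integer(dim(x)))
}

#' @rdname dwtForward
#' @param coeffs a [WaveletCoefficients-class].
#' @export
dwtInverse <- function(coeffs) {
  f <- waveletFilters(coeffs@wavelet)
  cur <- coeffs@approx
  for (j in rev(seq_len(coeffs@levels))) {
    d <- coeffs@details[[j]]
    lo <- t(idwtStepCols(t(cur), t(d$lh), f$rl, f$rh))
    hi <- t(idwtStepCols(t(d$hl), t(d$hh), f$rl, f$rh))
    cur <- idwtStepCols(lo, hi, f$rl, f$rh)
  }
  cur
}
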