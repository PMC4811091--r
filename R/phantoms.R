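# Synthetic tissue-like test images.

isPow2 <- function(n) n >= 1 && bitwAnd(n, n - 1L) == 0L

# Modified Shepp-Logan ellipse table: intensity, semi-axes (a, b), center
# (x0, y0), rotation in degrees; coordinates on [-1, 1]^2.
sheppLoganTable <- function() {
  matrix(c(
     1.0, 0.6900, 0.920,  0.00,  0.0000,   0,
    -0.8, 0.6624, 0.874,  0.00, -0.0184,   0,
    -0.2, 0.1100, 0.310,  0.22,  0.0000, -18,
    -0.2, 0.1600, 0.410, -0.22,  0.0000,  18,
     0.1, 0.2100, 0.250,  0.00,  0.3500,   0,
     0.1, 0.0460, 0.046,  0.00,  0.1000,   0,
     0.1, 0.0460, 0.046,  0.00, -0.1000,   0,
     0.1, 0.0460, 0.023, -0.08, -0.6050,   0,
     0.1, 0.0230, 0.023,  0.00, -0.6050,   0,
     0.1, 0.0230, 0.046,  0.06, -0.6050,   0),
    ncol = 6, byrow = TRUE)
}

ellipseMask <- function(H, W, A, a, b, x0, y0, phiDeg) {
  xs <- seq(-1, 1, length.out = W)
  ys <- seq(1, -1, length.out = H)   # row 1 = top
  X <- matrix(xs, H, W, byrow = TRUE) - x0
  Y <- matrix(ys, H, W) - y0
  phi <- phiDeg * pi / 180
  u <- X * cos(phi) + Y * sin(phi)
  v <- -X * sin(phi) + Y * cos(phi)
  (u / a)^2 + (v / b)^2 <= 1
}

# Seeded band-limited texture: white noise low-pass filtered in Fourier
# space (radius min(H,W)/8 around DC), standardized to unit standard
# deviation.
bandLimitedNoise <- function(H, W) {
  n <- matrix(stats::rnorm(H * W), H, W)
  Fk <- fftshift2(stats::fft(n))
  rr <- matrix(seq_len(H) - (floor(H / 2) + 1), H, W)
  cc <- matrix(seq_len(W) - (floor(W / 2) + 1), H, W, byrow = TRUE)
  keep <- sqrt(rr^2 + cc^2) <= min(H, W) / 8
  t <- Re(stats::fft(ifftshift2(Fk * keep), inverse = TRUE)) / (H * W)
  t / stats::sd(t)
}

#' Generate a synthetic tissue-like phantom
#'
#' Two kinds are available. \code{"shepp_logan"} is the classic analytic head
#' phantom (modified high-contrast intensity table), rescaled so the output
#' spans exactly [0, 255]. \code{"piecewise_texture"} superimposes smooth
#' elliptical tissue regions with seeded band-limited texture inside the
#' tissue support, emulating the gray-level texture variation of real tissue
#' that decimated wavelet methods are sensitive to; values are clipped to
#' [0, 255].
#'
#' Sizes are restricted to powers of two (>= 32) so that multilevel wavelet
#' decompositions divide evenly.
#'
#' @param size integer vector of length 1 or 2, the image height/width.
#' @param kind \code{"shepp_logan"} or \code{"piecewise_texture"}.
#' @param textureAmplitude standard deviation (gray levels) of the texture
#'   added inside tissue regions for the textured kind. Default 20, a visible
#'   but not dominant modulation on the 8-bit scale.
#' @param seed integer seed; the phantom is a pure function of its arguments.
#' @return numeric matrix in [0, 255].
#' @examples
#' p <- makePhantom(64, "shepp_logan")
#' range(p)
#' @export
makePhantom <- function(size, kind = c("shepp_logan", "piecewise_texture"),
                        textureAmplitude = 20, seed = 0L) {
  kind <- match.arg(kind)
  if (length(size) == 1L) size <- c(size, size)
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 32L) || !all(vapply(size, isPow2, logical(1))))
    stop("phantom size must be powers of two >= 32", call. = FALSE)
  if (textureAmplitude < 0) stop("'textureAmplitude' must be >= 0", call. = FALSE)
  H <- size[1L]; W <- size[2L]

  if (kind == "shepp_logan") {
    img <- matrix(0, H, W)
    tab <- sheppLoganTable()
    for (i in seq_len(nrow(tab)))
      img <- img + tab[i, 1L] * ellipseMask(H, W, tab[i, 1L], tab[i, 2L],
                                            tab[i, 3L], tab[i, 4L],
                                            tab[i, 5L], tab[i, 6L])
    rng <- range(img)
    img <- (img - rng[1L]) / (rng[2L] - rng[1L]) * 255
    return(img)
  }

  withSeed(seed, {
    img <- matrix(0, H, W)
    head <- ellipseMask(H, W, 1, 0.85, 0.9, 0, 0, 0)
    xs <- matrix(seq(-1, 1, length.out = W), H, W, byrow = TRUE)
    ys <- matrix(seq(1, -1, length.out = H), H, W)
    img[head] <- 90 * (1 + 0.25 * xs[head] - 0.15 * ys[head])
    regions <- list(
      list(lvl = 160, a = 0.40, b = 0.55, x0 = -0.25, y0 = 0.05, phi = 15,
           gx = -0.30, gy = 0.20),
      list(lvl = 60,  a = 0.30, b = 0.45, x0 = 0.35,  y0 = -0.1, phi = -20,
           gx = 0.35, gy = 0.25),
      list(lvl = 200, a = 0.15, b = 0.12, x0 = 0.05,  y0 = 0.45, phi = 0,
           gx = 0.20, gy = -0.30),
      list(lvl = 130, a = 0.18, b = 0.10, x0 = 0.1,   y0 = -0.55, phi = 30,
           gx = -0.25, gy = -0.20))
    for (r in regions) {
      m <- ellipseMask(H, W, 1, r$a, r$b, r$x0, r$y0, r$phi)
      # smooth intra-region gray-level gradient: tissue intensity is not
      # piecewise constant
      img[m] <- r$lvl * (1 + r$gx * (xs[m] - r$x0) + r$gy * (ys[m] - r$y0))
    }
    # partial-volume effect: blur boundaries slightly (periodic Gaussian,
    # sigma = 1 pixel)
    img <- gaussianBlurPeriodic(img, sigma = 1)
    if (textureAmplitude > 0) {
      tex <- bandLimitedNoise(H, W)
      img[head] <- img[head] + textureAmplitude * tex[head]
    }
    clip255(img)
  })
}

# FFT-based periodic Gaussian blur.
gaussianBlurPeriodic <- function(x, sigma) {
  H <- nrow(x); W <- ncol(x)
  fr <- c(0:(H / 2), -(H / 2 - 1):-1) / H
  fc <- c(0:(W / 2), -(W / 2 - 1):-1) / W
  G <- exp(-2 * pi^2 * sigma^2 * (matrix(fr^2, H, W) +
                                  matrix(fc^2, H, W, byrow = TRUE)))
  Re(stats::fft(stats::fft(x) * G, inverse = TRUE)) / (H * W)
}
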