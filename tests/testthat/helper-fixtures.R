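# Shared fixtures, built in code. Small sizes keep the default run fast;
# the acceptance tests use the full study sizes.

fixturePhantom <- local({
  cache <- new.env(parent = emptyenv())
  function(size = 64, kind = "piecewise_texture", seed = 7) {
    key <- paste(size, kind, seed, sep = "|")
    if (is.null(cache[[key]]))
      cache[[key]] <- makePhantom(size, kind, seed = seed)
    cache[[key]]
  }
})

# A seeded random image on the display scale (not tissue-like; used where
# the oracle is a round-trip identity that must hold for arbitrary inputs).
randomImage <- function(n, seed = 1) {
  withr::with_seed(seed, matrix(stats::runif(n * n, 0, 255), n, n))
}

# A small undersampled noisy acquisition used across solver tests.
fixtureAcquisition <- function(size = 64, accel = 5, sigma = 0.01, seed = 1) {
  x <- fixturePhantom(size)
  mask <- makeMask(c(size, size), accel, seed = seed)
  list(x = x, mask = mask,
       y = forwardModel(x, mask, noiseSigma = sigma, seed = seed + 1L))
}

complexInner <- function(a, b) sum(Conj(a) * b)
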