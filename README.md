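# ewistars

Compressed-sensing MRI reconstruction by **E**xponential **W**avelet
**I**terative **S**hrinkage-**T**hresholding **A**lgorithm with **R**andom
**S**hift (EWISTARS), for researchers simulating accelerated MRI
acquisition and comparing sparsity-driven reconstruction solvers.

An MRI scanner acquires samples of the image's 2-D Fourier transform
(k-space). Acquiring only a fraction of k-space shortens scans but
aliases the naive reconstruction; compressed sensing removes the aliasing
by exploiting sparsity in a transform domain. The acquisition model is

    y = U x + e,

with `U` the unitary 2-D DFT restricted to a sampling mask and `e` complex
Gaussian noise. With `Q = U W` (`W` the inverse sparsifying transform), the
solvers minimize

    S(ω) = ‖y − Qω‖₂² + λ‖ω‖₁

by iterative shrinkage-thresholding,

    ωₙ₊₁ ← Γ_{2λ/J}( ωₙ + (2/J)(a − A ωₙ) ),   a = Qᴴy,  A = QᴴQ,
    Γ_b(z) = sgn(z)·(|z| − min(b/2, |z|)),

with step bound `J ≥ 2 λmax(QᴴQ)`. EWISTARS augments this with two
components:

* an **exponential wavelet transform** — wavelet coefficients are jointly
  normalized to [0, 1] and passed `k` times through `v ↦ (eᵛ−1)/(e−1)`,
  enhancing significant coefficients and suppressing small ones, with exact
  inversion via the recorded normalization parameters;
* a **random circular shift** drawn freshly each iteration (cycle
  spinning), countering the translation variance of the decimated DWT.

The package also provides ISTA/FISTA baselines, synthetic tissue-like
phantoms, k-space mask generation (variable-density rows, radial spokes,
uniform), MAE/MSE/PSNR metrics, and experiment drivers for solver,
exponent-count and wavelet comparisons. See the methods vignette
(`vignettes/ewistars-methods.Rmd`) for the design decisions and their
rationale.

## Worked example

```r
library(ewistars)

x    <- makePhantom(128, "piecewise_texture", seed = 7)   # ground truth in [0, 255]
mask <- makeMask(c(128, 128), acceleration = 5, seed = 1) # 20% of k-space
mask
#> SamplingMask 128x128, scheme 'variable_density_random', acceleration 5.00 (kept 20.3%), seed 1

y  <- forwardModel(x, mask, noiseSigma = 0.01, seed = 2)  # simulated scan
zf <- Mod(applyUAdjoint(kspaceValues(y), mask))           # zero-filled baseline
psnr(x, zf)
#> 19.64

cfg <- solverConfig(maxIter = 100, ewtK = 6, wavelet = "bior4.4",
                    levels = 5, shiftEnabled = TRUE, seed = 3)
res <- ewistarsSolve(y, cfg, groundTruth = x)
res
#> ReconResult (ewistars): 128x128 estimate, 100 iterations, final cost 1.243e+05, final PSNR 20.24 dB

metricReport(x, estimate(res))
#> MetricReport: MAE 17.64, MSE 614.9, PSNR 20.24 dB over 16384 pixels
```

The reconstruction recovers 0.6 dB over the zero-filled baseline here; the
per-iteration `costTrace()`/`psnrTrace()` and the logged random shifts are
stored in the result, and rerunning with the same configuration reproduces
it bit for bit. `runComparison()`, `runKSweep()` and `runWaveletSweep()`
drive the multi-solver, exponent-count and wavelet studies and return tidy
data frames.

A command-line front end with `reconstruct`, `compare`, `ksweep` and
`wavsweep` subcommands is installed at
`system.file("scripts", "ewistars-cli.R", package = "ewistars")`.

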