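Package: ewistars
Title: Exponential Wavelet Iterative Shrinkage-Thresholding with Random
    Shift for Compressed-Sensing MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstruction of magnetic-resonance images from randomly
    undersampled k-space measurements by iterative shrinkage-thresholding
    with an exponential wavelet sparsifying transform and per-iteration
    random circular shifts (EWISTARS), together with the plain ISTA and
    FISTA wavelet baselines it is compared against. Includes synthetic
    tissue-like phantom generation, k-space undersampling and noise
    simulation with variable-density, radial and uniform masks, a
    periodized multilevel 2-D discrete wavelet transform for the
    Daubechies and biorthogonal spline families, MAE/MSE/PSNR
    reconstruction metrics, and experiment drivers for solver, exponent
    and wavelet comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    png,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
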