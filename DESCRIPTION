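Package: gpscan
Title: Gaussian Process Regression for Ultrasound Scanline Interpolation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scan conversion of ultrasound scanline (A-mode) data to
    brightness-mode images by exact Gaussian process (GP) regression with
    anisotropic squared-exponential and Matern covariance kernels.  Supports
    parallel (linear-array) and diverging (phased-array) scanline geometries,
    including a depth-dependent across-beam length scale for diverging beams,
    an overlapping-window patched GP with precomputed regression operators,
    reference interpolators (nearest neighbour, bilinear, cubic spline), a
    leave-N-out evaluation harness reporting PSNR/MAE/MSE, kernel length-scale
    selection by constrained mean-squared-error minimisation or closed-form
    grid heuristics, and a synthetic scanline phantom generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
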