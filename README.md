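# gpscan

Gaussian process (GP) regression for ultrasound scanline interpolation:
converting beamformed scanline (A-mode) data into dense B-mode images, with
a per-pixel uncertainty map as a by-product.

## The problem and who this is for

Ultrasound probes sample echo intensity densely *along* each beam but
sparsely *across* beams, and scan conversion must fill the gaps — in
Cartesian space for linear arrays (parallel beams) and in polar space for
phased/curvilinear arrays (beams diverging from an apex, where the physical
gap between beams grows with depth).  Conventional nearest-neighbour,
bilinear and cubic-spline rules use a handful of neighbours and ignore the
spatial statistics of the data.  This package is for ultrasound imaging and
image-analysis researchers who want a statistically grounded interpolator
(and its uncertainty), a windowed formulation fast enough to precompute per
probe, and a reproducible harness for comparing interpolators.

## The model

Scanline samples `y` at locations `x` are modelled as a zero-mean GP with an
anisotropic covariance `k` (squared exponential, or Matern with
`nu in {1/2, 3/2, 5/2}`; Matern 3/2 is the default) over the scaled distance
`r(x_i, x_j) = sqrt(sum_n (x_{i,n} - x_{j,n})^2 / l_n^2)`, with separate
length scales `l_r` along beams and `l_alpha` across beams.  With
`K = k(x,x)`, `K* = k(x,x*)`, `K** = k(x*,x*)` and noise `sigma_n^2`, the
interpolated image and its uncertainty are the GP posterior

    ybar* = K*^T (K + sigma_n^2 I)^-1 y
    V[y*] = diag(K**) - diag(K*^T (K + sigma_n^2 I)^-1 K*)

Key ingredients implemented here:

* **Geometry-aware length scales** — for diverging beams,
  `l_alpha(r_i) = l_alpha (|r|/2) / r_i` (1/r scaling with depth), and the
  closed-form grid heuristics `l_alpha = beam_pitch/3`,
  `l_r = k_N * sample_pitch` (`k_N` = scanline reduction factor), or a
  derivative-free MSE fit of `(l_r, l_alpha)`.
* **Patched (windowed) exact GP** — targets are grouped into small patches,
  each solved exactly from the 15 nearest observations in kernel-scaled
  distance; regression operators are precomputed per (grid, kernel) and
  replayed over frames with zero further factorizations.
* **Leave-N-out evaluation** — scanlines are withheld, reconstructed from
  the rest, and scored (PSNR/MAE/MSE) against the withheld lines only, for
  GP and the three reference interpolators.
* **Phantom generator** — GP draws with known hyperparameters, layered
  tissue, and speckle textures, so the whole pipeline is testable without
  clinical data.

## Worked example

Simulate a phantom at the size of a phased-array cardiac acquisition
(64 scanlines x 412 samples per beam), then compare interpolators at three
decimation levels:

```r
library(gpscan)

grid  <- scan_grid("diverging", n_scanlines = 64, n_samples = 412,
                   sample_pitch = 1, beam_pitch = (pi / 2) / 63)
frame <- generate_phantom(phantom_spec(grid, "gp_draw", seed = 1))
frame
#> <scan_frame> diverging, 64 scanlines x 412 samples, range [0.050, 0.950]
#>   provenance: phantom:gp_draw seed=1

report <- leave_n_out_study(frame, keep_counts = c(32, 16, 13),
                            window_size = 15)
print(as.data.frame(report), digits = 4)
#>      method n_keep psnr_db     mae     mse rel_psnr_db mean_variance
#> 1   nearest     32   17.41 0.10724 0.01816      0.0000            NA
#> 2  bilinear     32   19.15 0.08792 0.01216      1.7423            NA
#> 3    spline     32   18.42 0.09535 0.01439      1.0108            NA
#> 4        gp     32   19.32 0.08611 0.01169      1.9115      0.008278
#> 5   nearest     16   17.01 0.11222 0.01991      0.0000            NA
#> 6  bilinear     16   17.99 0.10054 0.01587      0.9854            NA
#> 7    spline     16   17.30 0.10889 0.01862      0.2913            NA
#> 8        gp     16   18.56 0.09348 0.01393      1.5519      0.007000
#> 9   nearest     13   16.90 0.11342 0.02041      0.0000            NA
#> 10 bilinear     13   17.82 0.10202 0.01651      0.9227            NA
#> 11   spline     13   17.13 0.11071 0.01936      0.2305            NA
#> 12       gp     13   18.48 0.09404 0.01418      1.5836      0.006789
```

Each row scores one method at one decimation level against the held-out
scanlines: `psnr_db` is `10 log10(1/MSE)` in dB (higher is better),
`rel_psnr_db` is the margin over the worst method in that column, and
`mean_variance` is the mean GP posterior variance (the uncertainty map,
absent for the baselines).  GP regression posts the highest PSNR and lowest
MAE in every column; as scanlines are removed, bilinear and spline sink
toward nearest neighbour while the GP holds its margin, and its mean
variance falls as more scanlines are kept.

A command-line wrapper over the same functions lives in `inst/cli/gpscan`
(subcommands `simulate`, `convert`, `evaluate`, `optimize`), reading and
writing PGM/PNG/CSV frames with JSON geometry sidecars.

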