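spec_se <- kernel_spec("squared_exponential", signal_variance = 2,
                       length_scale_r = 1.5, length_scale_alpha = 0.7)
spec_m32 <- kernel_spec("matern", nu = 1.5, signal_variance = 2,
                        length_scale_r = 1.5, length_scale_alpha = 0.7)

test_that("scaled distance matches its definition", {
  one <- point_set(c(1, 2), "beam_native")
  expect_equal(scaled_distance(one, one,
                               kernel_spec("matern", nu = 1.5,
                                           signal_variance = 1,
                                           length_scale_r = 3,
                                           length_scale_alpha = 2)),
               matrix(0, 1, 1))
  ab <- point_set(rbind(c(0, 0), c(3, 4)), "beam_native")
  iso <- kernel_spec("matern", nu = 1.5, signal_variance = 1,
                     length_scale_r = 1, length_scale_alpha = 1)
  expect_equal(scaled_distance(ab, ab, iso)[1, 2], 5)

  a <- random_points(20, seed = 11)
  b <- random_points(15, seed = 12)
  expect_equal(scaled_distance(a, b, spec_m32),
               oracle_scaled_distance(a, b, 1.5, 0.7), tolerance = 1e-12)
})

test_that("SE kernel matches the closed form pointwise", {
  x <- point_set(c(0.3, -1), "beam_native")
  expect_equal(se_kernel(x, x, spec_se)[1, 1], spec_se$signal_variance)
  # unit standardized distance along the r axis
  two <- point_set(rbind(c(0, 0), c(1.5, 0)), "beam_native")
  expect_equal(se_kernel(two, two, spec_se)[1, 2],
               2 * exp(-1 / 2), tolerance = 1e-12)
  a <- random_points(12, seed = 3); b <- random_points(9, seed = 4)
  K <- se_kernel(a, b, spec_se)
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b))) {
      d2 <- (a[i, 1] - b[j, 1])^2 / 1.5^2 + (a[i, 2] - b[j, 2])^2 / 0.7^2
      expect_equal(K[i, j], 2 * exp(-d2 / 2), tolerance = 1e-12)
    }
})

test_that("Matern closed forms agree with the gamma/Bessel definition", {
  r <- c(0.1, 0.5, 1, 3)
  along_r <- point_set(cbind(c(0, r) * 1.5, 0), "beam_native")
  for (nu in c(0.5, 1.5, 2.5)) {
    sp <- kernel_spec("matern", nu = nu, signal_variance = 2,
                      length_scale_r = 1.5, length_scale_alpha = 0.7)
    K <- matern_kernel(along_r, along_r, sp)
    expect_equal(K[1, -1], oracle_matern(r, nu, 2), tolerance = 1e-10)
    expect_equal(K[1, 1], 2)                 # r -> 0 limit is sigma^2
  }
})

test_that("Matern nu = 1/2 is the exponential kernel", {
  r <- seq(0, 10, by = 0.25)
  pts <- point_set(cbind(r * 1.5, 0), "beam_native")
  sp <- kernel_spec("matern", nu = 0.5, signal_variance = 2,
                    length_scale_r = 1.5, length_scale_alpha = 0.7)
  expect_equal(matern_kernel(pts, pts, sp)[1, ], 2 * exp(-r),
               tolerance = 1e-12)
  expect_error(kernel_spec("matern", nu = 2, signal_variance = 1,
                           length_scale_r = 1, length_scale_alpha = 1),
               "1/2, 3/2, 5/2")
})

test_that("kernel families are ordered in smoothness and bounded by sigma^2", {
  # Matern converges to SE from below as nu grows; the pointwise ordering
  # 3/2 <= 5/2 <= SE holds up to moderate scaled distances (beyond r ~ 1.9
  # the SE tail decays faster and crosses below the Matern tails)
  r <- seq(0.05, 1.5, by = 0.05)
  pts <- point_set(cbind(r * 1.5, 0), "beam_native")
  k32 <- matern_kernel(pts, pts, spec_m32)[1, ]
  sp52 <- spec_m32; sp52$nu <- 2.5
  k52 <- matern_kernel(pts, pts, sp52)[1, ]
  kse <- se_kernel(pts, pts, spec_se)[1, ]
  expect_true(all(k32 <= k52 & k52 <= kse))
  # positivity, sigma^2 bound and monotone decay hold at any distance
  rl <- seq(0.05, 10, by = 0.05)
  ptl <- point_set(cbind(rl * 1.5, 0), "beam_native")
  for (sp in list(spec_m32, sp52, spec_se)) {
    k <- kernel_matrix(ptl, ptl, sp)[1, ]
    expect_true(all(k > 0 & k <= 2 + 1e-12))
    expect_true(all(diff(k) <= 1e-12))       # non-increasing in r
  }
})

test_that("self-covariances are symmetric and PSD after jitter", {
  a <- random_points(40, seed = 9)
  for (sp in list(spec_se, spec_m32)) {
    K <- kernel_matrix(a, a, sp)
    expect_lt(max(abs(K - t(K))), 1e-12)
    ev <- eigen(K + diag(1e-10 * sp$signal_variance, nrow(K)),
                symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * sp$signal_variance)
  }
})

test_that("kernels are invariant to matched coordinate/length rescaling", {
  a <- random_points(15, seed = 21)
  b <- random_points(10, seed = 22)
  K1 <- kernel_matrix(a, b, spec_m32)
  c_r <- 3.7; c_a <- 0.21
  a2 <- point_set(cbind(a[, 1] * c_r, a[, 2] * c_a), "beam_native")
  b2 <- point_set(cbind(b[, 1] * c_r, b[, 2] * c_a), "beam_native")
  sp2 <- spec_m32
  sp2$length_scale_r <- sp2$length_scale_r * c_r
  sp2$length_scale_alpha <- sp2$length_scale_alpha * c_a
  expect_equal(kernel_matrix(a2, b2, sp2), K1, tolerance = 1e-12)
})

test_that("depth scaling of l_alpha follows the 1/r rule", {
  g <- scan_grid("diverging", 16, 101, 1, 0.03)   # |r| = 100
  sp <- kernel_spec("matern", nu = 1.5, signal_variance = 1,
                    length_scale_r = 2, length_scale_alpha = 0.01)
  len <- scanline_length(g)
  # spec's l_alpha is the mid-depth value
  expect_equal(depth_scaled_spec(sp, g, len / 2)$length_scale_alpha, 0.01)
  # at full depth: half the mid-depth value
  expect_equal(depth_scaled_spec(sp, g, len)$length_scale_alpha, 0.005)
  # doubling the depth halves l_alpha for any spec
  for (d in c(7, 31, 80)) {
    l1 <- depth_scaled_spec(sp, g, d)$length_scale_alpha
    l2 <- depth_scaled_spec(sp, g, 2 * d)$length_scale_alpha
    expect_equal(l2, l1 / 2, tolerance = 1e-12)
  }
  # the grid-heuristic value reproduces the printed closed form
  hsp <- kernel_spec("matern", nu = 1.5, signal_variance = 1,
                     length_scale_r = 2,
                     length_scale_alpha = g$beam_pitch / 3)
  for (d in c(10, 50, 90))
    expect_equal(depth_scaled_spec(hsp, g, d)$length_scale_alpha,
                 (1 / 3) * (len / (2 * d)) * g$beam_pitch, tolerance = 1e-12)
  expect_error(depth_scaled_spec(sp, g, 0), "depth")
  expect_error(depth_scaled_spec(sp, toy_parallel_grid(), 5), "diverging")
  # alternative quadratic reading stays switchable
  expect_equal(depth_scaled_spec(sp, g, 25,
                                 rule = "alt_quadratic")$length_scale_alpha,
               0.01 * len^2 / 25)
})

test_that("kernel specs round-trip through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  write_kernel_spec(spec_m32, path)
  back <- read_kernel_spec(path)
  expect_equal(back, spec_m32)
})
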