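# Shared fixtures and independent oracles.  Everything is generated in code;
# oracles deliberately use naive formulations (loops, explicit inverses,
# Bessel functions) independent of the package's computational paths.

toy_parallel_grid <- function(n_beams = 8, n_samples = 16,
                              dr = 1, da = 1) {
  scan_grid("parallel", n_scanlines = n_beams, n_samples = n_samples,
            sample_pitch = dr, beam_pitch = da)
}

toy_diverging_grid <- function(n_beams = 8, n_samples = 16, dr = 1,
                               da = 0.02, center = 0) {
  scan_grid("diverging", n_scanlines = n_beams, n_samples = n_samples,
            sample_pitch = dr, beam_pitch = da, sector_center = center)
}

random_points <- function(n, seed, lim = 5) {
  set.seed(seed)
  point_set(cbind(runif(n, -lim, lim), runif(n, -lim, lim)), "beam_native")
}

# brute-force double loop for the anisotropic scaled distance
oracle_scaled_distance <- function(a, b, l_r, l_a) {
  a <- unclass(a); b <- unclass(b)
  out <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b)))
      out[i, j] <- sqrt((a[i, 1] - b[j, 1])^2 / l_r^2 +
                          (a[i, 2] - b[j, 2])^2 / l_a^2)
  out
}

# Matern via the general gamma/Bessel form (base R besselK)
oracle_matern <- function(r, nu, sigma2) {
  out <- sigma2 * (2^(1 - nu) / gamma(nu)) *
    (sqrt(2 * nu) * r)^nu * besselK(sqrt(2 * nu) * r, nu)
  out[r == 0] <- sigma2
  out
}

# naive explicit-inverse GP posterior (mean and variance), replicating the
# package's standardization contract with independent code
oracle_gp <- function(obs, y, targets, spec) {
  obs <- unclass(obs); targets <- unclass(targets)
  mu_y <- mean(y); sd_y <- stats::sd(y)
  if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1
  mu_c <- colMeans(obs); sd_c <- apply(obs, 2, stats::sd)
  sd_c[!is.finite(sd_c) | sd_c == 0] <- 1
  os <- sweep(sweep(obs, 2, mu_c), 2, sd_c, "/")
  ts <- sweep(sweep(targets, 2, mu_c), 2, sd_c, "/")
  ys <- (y - mu_y) / sd_y
  kfun <- function(a, b) {
    out <- matrix(0, nrow(a), nrow(b))
    for (i in seq_len(nrow(a)))
      for (j in seq_len(nrow(b))) {
        r <- sqrt((a[i, 1] - b[j, 1])^2 / spec$length_scale_r^2 +
                    (a[i, 2] - b[j, 2])^2 / spec$length_scale_alpha^2)
        out[i, j] <- if (spec$family == "squared_exponential")
          spec$signal_variance * exp(-r^2 / 2)
        else oracle_matern(r, spec$nu, spec$signal_variance)
      }
    out
  }
  K <- kfun(os, os) + diag(spec$noise_variance + 1e-10 * spec$signal_variance,
                           nrow(os))
  Ks <- kfun(os, ts)
  Kinv <- solve(K)                      # explicit inverse, on purpose
  mean_std <- drop(t(Ks) %*% Kinv %*% ys)
  var_std <- spec$signal_variance - diag(t(Ks) %*% Kinv %*% Ks)
  list(mean = mean_std * sd_y + mu_y, variance = var_std * sd_y^2)
}

# small GP-drawn diverging phantom shared across expensive tests
shared_small_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- scan_grid("diverging", 32, 64, 1, (pi / 3) / 31)
      cache <<- generate_phantom(phantom_spec(g, "gp_draw", seed = 42))
    }
    cache
  }
})
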