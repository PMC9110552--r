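# Synthetic scanline phantoms.
#
# Three texture models cover the statistical regimes the interpolator is
# meant for: `gp_draw` samples a zero-mean GP with a known kernel on the
# observation lattice (the exact model the regression assumes, so recovery
# and ordering claims are testable); `layered_tissue` builds depth-wise
# bands with smooth transitions plus optional speckle (cardiac-like:
# piecewise-uniform dark blood / bright muscle); `speckle` is a smooth
# background modulated by multiplicative noise (leg-like high-frequency
# texture).  All generators are deterministic per seed and leave the global
# RNG state untouched.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Phantom specification
#'
#' @param grid a [scan_grid()].
#' @param texture `"gp_draw"`, `"layered_tissue"` or `"speckle"`.
#' @param kernel for `"gp_draw"`: a [kernel_spec()] whose length scales are
#'   in raw beam-native units (along-beam lengths, across-beam length or
#'   radians).  Default: Matern 3/2, `l_r = 3 * sample_pitch`,
#'   `l_alpha = (2/3) * beam_pitch`, unit signal variance, no noise.  The
#'   lateral scale equals one third of the beam spacing of a half-decimated
#'   lattice, i.e. the phantom mimics acquisitions for which the published
#'   l_alpha = beam_pitch / 3 grid relationship holds at the operating
#'   grids of a leave-N-out study; beams beyond the immediate neighbours
#'   then carry little shared signal, as in beamformed scanline data.
#' @param layers for `"layered_tissue"`: list with `depths` (boundary
#'   positions as fractions of the scanline length, increasing, in (0, 1)),
#'   `intensities` (one per band, length `length(depths) + 1`), and
#'   `smoothness` (transition width in samples).
#' @param noise_scale multiplicative speckle amplitude for
#'   `"layered_tissue"` (0 disables) and `"speckle"`.
#' @param seed integer random seed; always recorded with the frame.
#' @return object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(grid,
                         texture = c("gp_draw", "layered_tissue", "speckle"),
                         kernel = NULL, layers = NULL, noise_scale = 0.15,
                         seed = 1L) {
  stopifnot(inherits(grid, "scan_grid"))
  texture <- match.arg(texture)
  if (texture == "gp_draw" && is.null(kernel))
    kernel <- kernel_spec("matern", nu = 1.5, signal_variance = 1,
                          length_scale_r = 3 * grid$sample_pitch,
                          length_scale_alpha = (2 / 3) * grid$beam_pitch,
                          noise_variance = 0)
  if (texture == "layered_tissue" && is.null(layers))
    layers <- list(depths = c(1 / 3, 2 / 3),
                   intensities = c(0.2, 0.8, 0.4),
                   smoothness = 4)
  if (!is.null(layers)) {
    stopifnot(length(layers$intensities) == length(layers$depths) + 1L,
              all(diff(layers$depths) > 0),
              all(layers$depths > 0), all(layers$depths < 1))
  }
  structure(list(grid = grid, texture = texture, kernel = kernel,
                 layers = layers, noise_scale = noise_scale,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic scanline frame
#'
#' See [phantom_spec()] for the texture models.  GP draws use an exact
#' multivariate-normal sample (dense Cholesky) for lattices up to 10^4
#' points; larger lattices up to 10^5 points are sampled block-sequentially
#' along the beam axis, each block drawn from its exact conditional
#' distribution given a margin of previously sampled rows, which preserves
#' the local correlation structure the interpolation study depends on.
#' The raw draw is affinely mapped to `[0.05, 0.95]`.
#'
#' @param spec a [phantom_spec()].
#' @return a [scan_frame()]; the provenance tag records texture and seed.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid
  Z <- .with_seed(spec$seed, switch(spec$texture,
    gp_draw = .phantom_gp_draw(g, spec$kernel),
    layered_tissue = .phantom_layers(g, spec$layers, spec$noise_scale),
    speckle = .phantom_speckle(g, spec$noise_scale)))
  scan_frame(g, Z, provenance = sprintf("phantom:%s seed=%d",
                                        spec$texture, spec$seed))
}

.phantom_gp_draw <- function(grid, kernel) {
  n <- grid$n_samples * grid$n_scanlines
  if (n > 1e5)
    stop("gp_draw supports at most 1e5 lattice points; use a coarser grid")
  ns <- grid$n_samples; nb <- grid$n_scanlines
  co <- .coords_matrix(observation_coords(grid))
  if (n <= 1e4) {
    K <- kernel_matrix(co, co, kernel)
    fac <- .chol_psd(K, kernel$signal_variance)
    z <- drop(crossprod(fac$R, stats::rnorm(n)))
    Z <- matrix(z, ns, nb)
  } else {
    # block-sequential sampling along the sample axis: each row-block is
    # drawn from its exact conditional given `margin` previous rows
    rows_per_block <- max(2L, floor(3000 / nb))
    margin <- min(ns, max(4L, ceiling(3 * kernel$length_scale_r /
                                        grid$sample_pitch)))
    margin <- min(margin, rows_per_block)
    Z <- matrix(NA_real_, ns, nb)
    done <- 0L
    while (done < ns) {
      blk <- seq(done + 1L, min(done + rows_per_block, ns))
      bidx <- as.vector(outer(blk, (seq_len(nb) - 1L) * ns, "+"))
      B <- co[bidx, , drop = FALSE]
      if (done == 0L) {
        K <- kernel_matrix(B, B, kernel)
        fac <- .chol_psd(K, kernel$signal_variance)
        Z[blk, ] <- matrix(drop(crossprod(fac$R, stats::rnorm(length(bidx)))),
                           length(blk), nb)
      } else {
        cond_rows <- seq(done - margin + 1L, done)
        cidx <- as.vector(outer(cond_rows, (seq_len(nb) - 1L) * ns, "+"))
        A <- co[cidx, , drop = FALSE]
        a <- as.vector(Z[cond_rows, ])
        Kaa <- kernel_matrix(A, A, kernel)
        fac_a <- .chol_psd(Kaa, kernel$signal_variance)
        Kab <- kernel_matrix(A, B, kernel)
        W <- backsolve(fac_a$R, Kab, transpose = TRUE)      # = L^-1 Kab
        mu <- drop(crossprod(W, backsolve(fac_a$R, a, transpose = TRUE)))
        Kbb <- kernel_matrix(B, B, kernel) - crossprod(W)
        fac_b <- .chol_psd(Kbb, kernel$signal_variance)
        Z[blk, ] <- matrix(mu + drop(crossprod(fac_b$R,
                                               stats::rnorm(length(bidx)))),
                           length(blk), nb)
      }
      done <- done + length(blk)
    }
  }
  rng <- range(Z)
  if (rng[2] > rng[1]) Z <- (Z - rng[1]) / (rng[2] - rng[1]) * 0.9 + 0.05
  else Z[] <- 0.5
  Z
}

.phantom_layers <- function(grid, layers, noise_scale) {
  ns <- grid$n_samples; nb <- grid$n_scanlines
  depth_frac <- (seq_len(ns) - 1) / (ns - 1)
  w <- max(layers$smoothness, 1e-6) / (ns - 1)   # transition width, fraction
  prof <- rep(layers$intensities[1], ns)
  for (k in seq_along(layers$depths)) {
    s <- stats::plogis((depth_frac - layers$depths[k]) / w)
    prof <- prof + (layers$intensities[k + 1] - layers$intensities[k]) * s
  }
  Z <- matrix(prof, ns, nb)
  if (noise_scale > 0) {
    r <- matrix(stats::rnorm(ns * nb), ns, nb)
    r <- .smooth_cols(.smooth_cols(r, 1), 1)     # mildly correlated speckle
    Z <- Z * (1 + noise_scale * r / stats::sd(r))
  }
  pmin(pmax(Z, 0), 1)
}

.phantom_speckle <- function(grid, noise_scale) {
  ns <- grid$n_samples; nb <- grid$n_scanlines
  u <- (seq_len(ns) - 1) / (ns - 1)
  v <- (seq_len(nb) - 1) / (nb - 1)
  bg <- matrix(0, ns, nb)
  for (k in 1:4) {                        # smooth anatomy-scale background
    fu <- stats::runif(1, 0.5, 2.5); fv <- stats::runif(1, 0.5, 2.5)
    ph <- stats::runif(2, 0, 2 * pi)
    bg <- bg + outer(cos(2 * pi * fu * u + ph[1]),
                     cos(2 * pi * fv * v + ph[2])) / k
  }
  bg <- 0.5 + 0.3 * bg / max(abs(bg))
  # Rayleigh-distributed multiplicative speckle, unit mean
  ray <- matrix(sqrt(-2 * log(stats::runif(ns * nb))), ns, nb) / sqrt(pi / 2)
  Z <- bg * (1 + noise_scale * (ray - 1))
  pmin(pmax(Z, 0), 1)
}

.smooth_cols <- function(m, k) {
  n <- nrow(m)
  out <- m
  for (i in seq_len(k)) {
    out <- (rbind(out[1, , drop = FALSE], out[-n, , drop = FALSE]) +
            out +
            rbind(out[-1, , drop = FALSE], out[n, , drop = FALSE])) / 3
  }
  out
}

#' Shared-phantom leave-N-out fixture
#'
#' Generates one phantom frame and decimates it at every requested keep
#' count, so all decimation levels share the same underlying realization.
#'
#' @param spec a [phantom_spec()].
#' @param keep_counts integer vector of scanline counts to keep.
#' @return list with `frame` (the full [scan_frame()]) and `decimated`, a
#'   named list of [decimate()] results (names are the keep counts).
#' @export
paired_study_fixture <- function(spec, keep_counts) {
  frame <- generate_phantom(spec)
  dec <- lapply(as.integer(keep_counts), function(k) decimate(frame, k))
  names(dec) <- as.character(keep_counts)
  list(frame = frame, decimated = dec)
}
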