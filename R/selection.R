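# Kernel length-scale selection: either the closed-form grid heuristics or
# constrained minimization of held-out mean squared error.

#' Closed-form length-scale heuristics from grid geometry
#'
#' Observed relationships between the optimal kernel lengths and the lattice
#' parameters, usable instead of running the MSE optimization:
#' for parallel scanlines `l_alpha = beam_pitch / 3` and
#' `l_r = k_N * sample_pitch`, where `k_N` is the leave-N-out reduction
#' factor (e.g. `k_N = 4` when one quarter of the scanlines are kept); for
#' diverging scanlines `l_r` is the same and the across-beam scale is
#' depth-dependent,
#' `l_alpha(r_i) = (1/3) (|r| / (2 r_i)) beam_pitch`,
#' i.e. the parallel value at mid-depth scaled by 1/r.
#'
#' With `std` supplied, the pitches are first mapped into standardized
#' coordinate units (the unit system the GP path evaluates kernels in).
#'
#' @param grid a [scan_grid()].
#' @param k_N reduction factor (>= 1).
#' @param depth observation depth(s) for diverging grids (required there);
#'   pass `scanline_length(grid) / 2` for the mid-depth value.
#' @param std optional `"std_params"`; when given, the returned scales are in
#'   standardized units.
#' @return named numeric vector `c(l_r = ..., l_alpha = ...)`; `l_alpha` has
#'   one entry per `depth` for diverging grids.
#' @export
heuristic_length_scales <- function(grid, k_N = 1, depth = NULL, std = NULL) {
  stopifnot(inherits(grid, "scan_grid"))
  if (!is.finite(k_N) || k_N < 1) stop("`k_N` must be >= 1")
  dr <- grid$sample_pitch
  da <- grid$beam_pitch
  if (!is.null(std)) {
    dr <- dr / std$coord_scale[1]
    da <- da / std$coord_scale[2]
  }
  l_r <- k_N * dr
  if (grid$geometry == "parallel")
    return(c(l_r = l_r, l_alpha = da / 3))
  if (is.null(depth))
    stop("diverging grids need `depth` (the heuristic l_alpha is depth-dependent)")
  if (any(!is.finite(depth)) || any(depth <= 0)) stop("`depth` must be > 0")
  la <- (da / 3) * (scanline_length(grid) / 2) / depth
  if (length(depth) == 1L) c(l_r = l_r, l_alpha = unname(la))
  else c(l_r = l_r, l_alpha = unname(la))
}

#' Fit kernel length scales by held-out MSE minimization
#'
#' Minimizes the mean squared reconstruction error of the patched GP at the
#' held-out scanlines of a leave-N-out decimation, over `(l_r, l_alpha)`
#' subject to positivity, with a derivative-free Nelder-Mead search in
#' log-length space (the landscape is convex but nearly flat around the
#' optimum, which rules out finite-difference gradients through the patched
#' pipeline).  The decimation, targets and patch plan are fixed before the
#' search, so the objective is deterministic given the frame.
#'
#' @param frame a [scan_frame()] (treated as ground truth).
#' @param n_keep number of scanlines kept for the reconstruction.
#' @param spec optional [kernel_spec()] supplying family, `nu`, `sigma^2`
#'   and `sigma_n^2` (defaults to Matern 3/2 with the geometry's default
#'   noise).
#' @param bounds 2 x 2 matrix `rbind(l_r = c(lo, hi), l_alpha = c(lo, hi))`
#'   in standardized units; defaults to `init` times `c(1/10, 10)`.
#' @param init initial `(l_r, l_alpha)` in standardized units; defaults to
#'   the grid heuristics at the cell's reduction factor.
#' @param window_size,targets_per_patch passed to [plan_patches()].
#' @param maxit Nelder-Mead iteration cap.
#' @param reltol relative convergence tolerance on the objective.
#' @return object of class `"length_scale_fit"`: `l_r`, `l_alpha`
#'   (standardized units), `objective` (MSE at the fit), `init`,
#'   `init_objective`, `evaluations`, `converged`, `bounds`, `std` (the
#'   standardization the units refer to).
#' @export
optimize_length_scales <- function(frame, n_keep, spec = NULL, bounds = NULL,
                                   init = NULL, window_size = 15L,
                                   targets_per_patch = 8L,
                                   maxit = 200L, reltol = 1e-3) {
  stopifnot(inherits(frame, "scan_frame"))
  g <- frame$grid
  if (is.null(spec))
    spec <- kernel_spec("matern", nu = 1.5, signal_variance = 1,
                        length_scale_r = 1, length_scale_alpha = 1,
                        noise_variance = default_noise_variance(g$geometry))
  dec <- decimate(frame, n_keep)
  ho <- dec$held_out
  if (length(ho) == 0L) stop("`n_keep` leaves no scanlines to score against")
  full_obs <- observation_coords(g)
  idx <- as.vector(outer(seq_len(g$n_samples), (ho - 1L) * g$n_samples, "+"))
  targets <- full_obs[idx]
  truth <- as.vector(frame$intensities[, ho, drop = FALSE])
  std <- grid_std_params(dec$frame$grid)
  if (is.null(init)) {
    h <- heuristic_length_scales(dec$frame$grid, k_N = dec$k_N,
                                 depth = if (g$geometry == "diverging")
                                   scanline_length(g) / 2 else NULL,
                                 std = std)
    init <- c(h[["l_r"]], h[["l_alpha"]])
  }
  init <- as.numeric(init)
  if (any(init <= 0)) stop("`init` length scales must be > 0")
  # the plan (and with it the window metric) is fixed at `init` before the
  # search so the objective is a deterministic function of the length scales
  plan <- plan_patches(dec$frame$grid, targets, window_size = window_size,
                       targets_per_patch = targets_per_patch,
                       metric_scales = init)
  if (is.null(bounds)) bounds <- cbind(init / 10, init * 10)
  bounds <- matrix(as.numeric(bounds), 2, 2)
  if (any(bounds <= 0) || any(bounds[, 1] >= bounds[, 2]))
    stop("`bounds` must be positive with lower < upper")
  init <- pmin(pmax(init, bounds[, 1]), bounds[, 2])
  lb <- log(bounds)

  n_eval <- 0L
  objective <- function(logl) {
    # box constraint via a large penalty growing with the violation
    viol <- sum(pmax(lb[, 1] - logl, 0) + pmax(logl - lb[, 2], 0))
    if (viol > 0) return(1e6 * (1 + viol))
    n_eval <<- n_eval + 1L
    sp <- spec
    sp$length_scale_r <- exp(logl[1])
    sp$length_scale_alpha <- exp(logl[2])
    ops <- build_operators(plan, dec$frame$grid, sp)
    est <- patched_predict(ops, dec$frame, plan)
    mse(truth, est$values)
  }

  f0 <- objective(log(init))
  opt <- stats::optim(log(init), objective, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol))
  fit_l <- exp(opt$par)
  fit_obj <- opt$value
  if (fit_obj > f0) { fit_l <- init; fit_obj <- f0 }   # descent contract
  structure(list(l_r = fit_l[1], l_alpha = fit_l[2], objective = fit_obj,
                 init = init, init_objective = f0,
                 evaluations = n_eval, converged = opt$convergence == 0L,
                 bounds = bounds, n_keep = n_keep, std = std),
            class = "length_scale_fit")
}

#' @export
print.length_scale_fit <- function(x, ...) {
  cat(sprintf("<length_scale_fit> l_r=%.5g, l_alpha=%.5g (standardized units)\n",
              x$l_r, x$l_alpha))
  cat(sprintf("  held-out MSE %.6g (init %.6g), %d evaluations, converged: %s\n",
              x$objective, x$init_objective, x$evaluations, x$converged))
  invisible(x)
}
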