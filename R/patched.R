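# Patched (windowed) exact GP regression.
#
# The covariance families used here decay quickly with distance, so outside a
# local window the contribution of an observation to a prediction is
# negligible.  The target set is partitioned into patches; each patch draws
# its observations from the `window_size` nearest observations (in
# standardized beam-native distance) to the patch centroid, and the exact GP
# is solved per patch.  Windows overlap across patches; target ownership is
# exclusive, so every target receives exactly one mean and one variance.
# Because the regression weights depend only on geometry and kernel, they can
# be precomputed once per (grid, spec, plan) and replayed over any number of
# frames without further factorizations.

.plan_fingerprint <- function(grid, window_size, targets_per_patch, n_targets) {
  paste(grid$geometry, grid$n_scanlines, grid$n_samples,
        format(grid$sample_pitch, digits = 17),
        format(grid$beam_pitch, digits = 17),
        format(grid$depth_offset, digits = 17),
        format(grid$sector_center, digits = 17),
        if (is.null(grid$beam_coords)) "regular"
        else paste(format(grid$beam_coords, digits = 17), collapse = ","),
        window_size, targets_per_patch, n_targets, sep = "|")
}

.spec_fingerprint <- function(spec, depth_scaling) {
  paste(spec$family, format(spec$nu), format(spec$signal_variance, digits = 17),
        format(spec$length_scale_r, digits = 17),
        format(spec$length_scale_alpha, digits = 17),
        format(spec$noise_variance, digits = 17), depth_scaling, sep = "|")
}

#' Partition targets into patches and select observation windows
#'
#' Deterministically groups the target points into compact patches of about
#' `targets_per_patch` points (rank-balanced cells in standardized
#' beam-native coordinates) and attaches to each patch the `window_size`
#' observations nearest to the patch centroid in kernel-scaled distance
#' (coordinates divided by the kernel length scales).  Kernel-scaled
#' nearness selects the observations most correlated with the patch, which
#' is what makes a 15-observation window track the full GP; plain
#' standardized distance would pick a window collapsed onto a single beam
#' whenever samples are much denser along beams than across them, as they
#' are on every scanline lattice.  The plan depends only on geometry and the
#' metric, never on intensities.  If `window_size` is at least the total
#' number of observations the plan collapses to a single patch, which makes
#' [patched_predict()] identical to the full exact GP.
#'
#' @param grid the (possibly decimated) [scan_grid()] carrying the
#'   observations.
#' @param targets a [point_set()] of prediction locations in the beam-native
#'   frame.
#' @param window_size number of observations per window (>= 2; default 15,
#'   the value beyond which enlarging the window gives negligible PSNR gain).
#' @param targets_per_patch approximate number of targets per patch.
#' @param metric_scales length-2 numeric `(l_r, l_alpha)` in standardized
#'   units defining the kernel-scaled window metric; pass the length scales
#'   of the kernel the operators will use.  Defaults to the grid heuristics
#'   ([heuristic_length_scales()]) at `k_N = 1` (mid-depth for diverging
#'   grids), which depend on geometry only.
#' @return object of class `"patch_plan"`: list with `patches` (each holding
#'   `targets`, `obs`, `center`, `center_depth`), the standardization used,
#'   and bookkeeping fields.
#' @export
plan_patches <- function(grid, targets, window_size = 15L,
                         targets_per_patch = 8L, metric_scales = NULL) {
  stopifnot(inherits(grid, "scan_grid"))
  tc <- .coords_matrix(targets)
  m <- nrow(tc)
  if (m < 1L) stop("no targets to plan for")
  window_size <- as.integer(window_size)
  if (window_size < 2L) stop("`window_size` must be >= 2")
  obs <- observation_coords(grid)
  n_obs <- nrow(obs)
  if (window_size > n_obs) {
    warning(sprintf("window_size %d exceeds the %d available observations; %s",
                    window_size, n_obs, "using all observations"))
    window_size <- n_obs
  }
  std <- grid_std_params(grid)
  os <- standardize_points(obs, std)
  ts <- standardize_points(tc, std)
  if (is.null(metric_scales)) {
    h <- heuristic_length_scales(grid, k_N = 1,
                                 depth = if (grid$geometry == "diverging")
                                   scanline_length(grid) / 2 else NULL,
                                 std = std)
    metric_scales <- c(h[["l_r"]], h[["l_alpha"]])
  }
  metric_scales <- as.numeric(metric_scales)
  if (length(metric_scales) != 2L || any(!is.finite(metric_scales)) ||
      any(metric_scales <= 0))
    stop("`metric_scales` must be two positive numbers")

  if (window_size >= n_obs) {
    groups <- list(seq_len(m))                       # single patch: full GP
  } else {
    n_patch <- max(1L, ceiling(m / targets_per_patch))
    span_r <- diff(range(ts[, 1])); span_a <- diff(range(ts[, 2]))
    if (span_r <= 0) span_r <- 1e-12
    if (span_a <= 0) span_a <- 1e-12
    nb_a <- max(1L, min(n_patch, round(sqrt(n_patch * span_a / span_r))))
    nb_r <- max(1L, ceiling(n_patch / nb_a))
    # rank-balanced 2D cells: bin across-beam first, then along-beam within
    rk_a <- rank(ts[, 2], ties.method = "first")
    bin_a <- ceiling(rk_a * nb_a / m)
    groups <- list()
    for (ba in sort(unique(bin_a))) {
      idx <- which(bin_a == ba)
      rk_r <- rank(ts[idx, 1], ties.method = "first")
      bin_r <- ceiling(rk_r * nb_r / length(idx))
      for (br in sort(unique(bin_r)))
        groups[[length(groups) + 1L]] <- idx[bin_r == br]
    }
  }

  patches <- vector("list", length(groups))
  for (p in seq_along(groups)) {
    tidx <- groups[[p]]
    ctr <- colMeans(ts[tidx, , drop = FALSE])
    d2 <- ((os[, 1] - ctr[1]) / metric_scales[1])^2 +
      ((os[, 2] - ctr[2]) / metric_scales[2])^2
    oidx <- order(d2)[seq_len(window_size)]           # deterministic ties
    depth <- ctr[1] * std$coord_scale[1] + std$coord_shift[1]
    patches[[p]] <- list(targets = tidx, obs = sort(oidx), center = ctr,
                         center_depth = max(depth, .Machine$double.eps))
  }
  structure(list(patches = patches, window_size = window_size,
                 n_obs = n_obs, n_targets = m, std = std,
                 obs_std = os, target_std = ts,
                 metric_scales = metric_scales,
                 fingerprint = paste(.plan_fingerprint(grid, window_size,
                                                       targets_per_patch, m),
                                     paste(format(metric_scales, digits = 17),
                                           collapse = ","), sep = "|")),
            class = "patch_plan")
}

#' @export
print.patch_plan <- function(x, ...) {
  cat(sprintf("<patch_plan> %d patches, window %d of %d observations, %d targets\n",
              length(x$patches), x$window_size, x$n_obs, x$n_targets))
  invisible(x)
}

#' Precompute per-patch GP regression operators
#'
#' For each patch of a [plan_patches()] plan, factorizes the window covariance
#' `K + sigma_n^2 I` once and stores the weight matrix
#' `W = K*^T (K + sigma_n^2 I)^-1` together with the prior and cross-term
#' variance diagonals.  Operators depend only on coordinates and the kernel
#' spec, never on intensities, so a fixed grid/spec pair can replay them over
#' any number of frames with plain matrix-vector products (no further
#' factorizations; see [gp_chol_count()]).
#'
#' On diverging grids the across-beam length scale is depth-scaled
#' ([depth_scaled_spec()]) per patch: the whole window (observation and
#' cross covariances alike) uses the length scale at the patch's centre
#' depth.  Patches are small along the beam, so the within-patch variation
#' of the 1/r rule is negligible, and using one consistent kernel per window
#' keeps every patch a valid GP with a nonnegative posterior variance.
#'
#' @param plan a `"patch_plan"`.
#' @param grid the [scan_grid()] the plan was built from.
#' @param spec a [kernel_spec()] (length scales in standardized units).
#' @param depth_scaling apply the 1/r across-beam rule; defaults to `TRUE`
#'   for diverging grids.
#' @param jitter initial diagonal jitter as a fraction of `sigma^2`.
#' @return list of `"gp_operator"` objects, one per patch, carrying
#'   `weights`, `prior_var`, `q_diag`, `var_diag`, index sets and a
#'   fingerprint.
#' @export
build_operators <- function(plan, grid, spec,
                            depth_scaling = NULL, jitter = 1e-10) {
  stopifnot(inherits(plan, "patch_plan"), inherits(grid, "scan_grid"),
            inherits(spec, "kernel_spec"))
  if (is.null(depth_scaling)) depth_scaling <- grid$geometry == "diverging"
  if (depth_scaling && grid$geometry != "diverging")
    stop("depth scaling requires a diverging grid")
  s2 <- spec$signal_variance
  sfp <- .spec_fingerprint(spec, depth_scaling)
  ops <- vector("list", length(plan$patches))
  for (p in seq_along(plan$patches)) {
    pt <- plan$patches[[p]]
    O <- plan$obs_std[pt$obs, , drop = FALSE]
    T <- plan$target_std[pt$targets, , drop = FALSE]
    spec_c <- if (depth_scaling)
      depth_scaled_spec(spec, grid, pt$center_depth) else spec
    K <- kernel_matrix(O, O, spec_c)
    diag(K) <- diag(K) + spec$noise_variance
    fac <- tryCatch(.chol_psd(K, s2, jitter0 = jitter), error = function(e)
      stop(sprintf("patch %d: %s", p, conditionMessage(e))))
    rm(K)
    # chunk targets so large single-patch (full-GP) problems keep the
    # working set at the weight matrix plus the Cholesky factor
    n_t <- nrow(T)
    chunk <- max(1L, min(n_t, floor(2e7 / nrow(O))))
    W_op <- matrix(0, n_t, nrow(O))
    q <- numeric(n_t)
    for (j0 in seq(1L, n_t, by = chunk)) {
      jj <- j0:min(j0 + chunk - 1L, n_t)
      Ks <- kernel_matrix(O, T[jj, , drop = FALSE], spec_c)
      X <- backsolve(fac$R, backsolve(fac$R, Ks, transpose = TRUE))
      q[jj] <- colSums(Ks * X)
      W_op[jj, ] <- t(X)
    }
    v <- s2 - q
    if (any(v < -1e-8 * s2))
      stop(sprintf("patch %d: posterior variance below tolerance", p))
    ops[[p]] <- structure(list(weights = W_op, prior_var = rep(s2, length(q)),
                               q_diag = q, var_diag = pmax(v, 0),
                               obs = pt$obs, targets = pt$targets,
                               jitter = fac$jitter,
                               fingerprint = paste(plan$fingerprint, sfp, p,
                                                   sep = "#")),
                          class = "gp_operator")
  }
  ops
}

#' Apply precomputed operators to a frame
#'
#' Runs the patched GP over one [scan_frame()]: the frame's intensities are
#' standardized (frame mean and standard deviation, so every window shares
#' the same zero-mean prior the full GP would use), each patch's precomputed
#' weight matrix is applied to its window, and the results are
#' de-standardized and assembled into full-length posterior mean and
#' variance vectors.  Each target is owned by exactly one patch.
#'
#' @param operators list of `"gp_operator"` built by [build_operators()].
#' @param frame a [scan_frame()] on the plan's grid.
#' @param plan the `"patch_plan"` the operators were built from.
#' @return an `"interpolation_result"` (see [interpolation_result()]) with
#'   `method = "gp"` and a variance vector.
#' @export
patched_predict <- function(operators, frame, plan) {
  stopifnot(inherits(frame, "scan_frame"), inherits(plan, "patch_plan"))
  v <- as.vector(frame$intensities)
  if (length(v) != plan$n_obs)
    stop("frame does not match the plan's observation lattice")
  mu <- mean(v)
  sw <- stats::sd(v)
  if (!is.finite(sw) || sw == 0) sw <- 1
  vs <- (v - mu) / sw
  mean_out <- numeric(plan$n_targets)
  var_out <- numeric(plan$n_targets)
  for (p in seq_along(operators)) {
    op <- operators[[p]]
    mean_out[op$targets] <- mu + sw * drop(op$weights %*% vs[op$obs])
    var_out[op$targets] <- sw^2 * op$var_diag
  }
  interpolation_result(mean_out, variance = var_out, method = "gp",
                       fingerprint = plan$fingerprint)
}
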