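# internal instrumentation: number of Cholesky factorizations performed
.gp_state <- new.env(parent = emptyenv())
.gp_state$chol_count <- 0L

#' Cholesky factorization counter
#'
#' The patched-GP path precomputes its regression operators so that applying
#' them to further frames performs no factorization at all.  This counter
#' exposes that behaviour: it increments once per successful Cholesky
#' factorization anywhere in the package.
#'
#' @param reset if `TRUE`, reset the counter to zero (returns the old value).
#' @return integer count.
#' @export
gp_chol_count <- function(reset = FALSE) {
  n <- .gp_state$chol_count
  if (reset) .gp_state$chol_count <- 0L
  n
}

# K %*% v without materializing K for large point sets
.kernel_matvec <- function(coords, spec, v) {
  n <- nrow(coords)
  if (n * n <= 2e7) return(drop(kernel_matrix(coords, coords, spec) %*% v))
  out <- numeric(n)
  step <- max(1L, floor(2e7 / n))
  for (i0 in seq(1L, n, by = step)) {
    ii <- i0:min(i0 + step - 1L, n)
    out[ii] <- drop(kernel_matrix(coords[ii, , drop = FALSE], coords,
                                  spec) %*% v)
  }
  out
}

# Cholesky of a PSD-after-jitter matrix with escalation: start from
# jitter0 * sigma2 and multiply by 10 at most max_esc times.
.chol_psd <- function(K, sigma2, jitter0 = 1e-10, max_esc = 6L) {
  jit <- jitter0 * sigma2
  for (k in 0:max_esc) {
    R <- tryCatch(chol(K + diag(jit, nrow(K))), error = function(e) NULL)
    if (!is.null(R)) {
      .gp_state$chol_count <- .gp_state$chol_count + 1L
      return(list(R = R, jitter = jit, min_pivot = min(diag(R))))
    }
    jit <- jit * 10
  }
  stop(sprintf(paste0("Cholesky factorization failed after jitter escalation",
                      " to %.3g (matrix size %d, sigma2 %.3g)"),
               jit, nrow(K), sigma2))
}

#' Standardize intensities and coordinates
#'
#' Shifts and scales the intensity vector to zero mean and unit variance, and
#' each coordinate axis likewise, recording the parameters for exact
#' inversion.  A constant intensity vector gets scale 1 and a `constant` flag
#' rather than an error.  Standardization absorbs the zero-mean GP prior and
#' keeps the linear algebra well conditioned.
#'
#' @param values numeric vector of intensities.
#' @param coords a [point_set()] or M x 2 matrix.
#' @return list with `values`, `coords` (standardized) and `params`, an
#'   object of class `"std_params"` with fields `value_shift`, `value_scale`,
#'   `coord_shift`, `coord_scale`, `constant`.
#' @export
standardize <- function(values, coords) {
  coords <- .coords_matrix(coords)
  values <- as.numeric(values)
  if (length(values) != nrow(coords))
    stop("`values` and `coords` must have matching lengths")
  vs <- mean(values)
  vsc <- stats::sd(values)
  constant <- FALSE
  if (!is.finite(vsc) || vsc == 0) { vsc <- 1; constant <- TRUE }
  cs <- colMeans(coords)
  csc <- apply(coords, 2, stats::sd)
  csc[!is.finite(csc) | csc == 0] <- 1
  params <- structure(list(value_shift = vs, value_scale = vsc,
                           coord_shift = cs, coord_scale = csc,
                           constant = constant),
                      class = "std_params")
  list(values = (values - vs) / vsc,
       coords = standardize_points(coords, params),
       params = params)
}

#' @rdname standardize
#' @param params a `"std_params"` object.
#' @export
standardize_points <- function(coords, params) {
  coords <- .coords_matrix(coords)
  sweep(sweep(coords, 2, params$coord_shift, "-"), 2, params$coord_scale, "/")
}

#' @rdname standardize
#' @export
destandardize_values <- function(values, params) {
  values * params$value_scale + params$value_shift
}

#' Coordinate standardization of a grid
#'
#' Standardization parameters computed from the observation lattice of a grid
#' (coordinates only; intensity shift/scale are identity placeholders).  The
#' patched-GP path standardizes all coordinates with one such object so that
#' kernel length scales mean the same thing in every window.
#'
#' @param grid a [scan_grid()].
#' @return a `"std_params"` object.
#' @export
grid_std_params <- function(grid) {
  co <- .coords_matrix(observation_coords(grid))
  structure(list(value_shift = 0, value_scale = 1,
                 coord_shift = colMeans(co),
                 coord_scale = apply(co, 2, stats::sd),
                 constant = FALSE),
            class = "std_params")
}

#' Exact GP posterior prediction
#'
#' Computes the GP posterior mean
#' `ybar* = K*^T (K + sigma_n^2 I)^-1 y`
#' and pointwise variance
#' `V[y*] = diag(K**) - diag(K*^T (K + sigma_n^2 I)^-1 K*)`
#' at the target points, working in standardized space through a Cholesky
#' factorization (never an explicit inverse) and de-standardizing the
#' results.  Only the diagonal of `K**` is formed.  Kernel length scales in
#' `spec` are interpreted in standardized coordinate units.
#'
#' Negative variances within floating-point tolerance of zero are clamped to
#' zero; a violation beyond `-1e-8 * sigma^2` aborts.
#'
#' @param obs_coords observation locations ([point_set()] or M x 2 matrix).
#' @param obs_values observed intensities (length M).
#' @param target_coords prediction locations, same frame as `obs_coords`.
#' @param spec a [kernel_spec()].
#' @param coord_std optional `"std_params"` fixing the coordinate
#'   standardization; by default it is computed from the observations.
#' @param value_std optional `list(shift, scale)` fixing the intensity
#'   standardization (e.g. a whole frame's mean and standard deviation, as
#'   the patched path uses); by default computed from `obs_values`.
#' @param jitter initial diagonal jitter, as a fraction of `sigma^2`;
#'   escalates tenfold on factorization failure, at most six times.
#' @param compute_variance set `FALSE` to skip the posterior variance (the
#'   mean costs one triangular solve per target block; the variance costs a
#'   second, which dominates on large problems).
#' @return object of class `"gp_posterior"`: list with `mean`, `variance`
#'   (de-standardized; `NULL` if not computed), and `diagnostics`
#'   (`jitter`, `min_pivot`).
#' @export
gp_predict <- function(obs_coords, obs_values, target_coords, spec,
                       coord_std = NULL, value_std = NULL, jitter = 1e-10,
                       compute_variance = TRUE) {
  stopifnot(inherits(spec, "kernel_spec"))
  oc <- .coords_matrix(obs_coords)
  tc <- .coords_matrix(target_coords)
  y <- as.numeric(obs_values)
  if (length(y) != nrow(oc)) stop("`obs_values` length must match observations")
  if (length(y) < 1L) stop("at least one observation is required")
  if (inherits(obs_coords, "point_set") && inherits(target_coords, "point_set") &&
      !identical(attr(obs_coords, "frame"), attr(target_coords, "frame")))
    stop("observations and targets must be in the same frame")

  if (is.null(coord_std)) {
    std <- standardize(y, oc)
    os <- std$coords; params <- std$params
  } else {
    params <- coord_std
    os <- standardize_points(oc, coord_std)
  }
  if (is.null(value_std)) {
    if (is.null(coord_std)) value_std <- list(shift = params$value_shift,
                                              scale = params$value_scale)
    else {
      vs <- mean(y); vsc <- stats::sd(y)
      if (!is.finite(vsc) || vsc == 0) vsc <- 1
      value_std <- list(shift = vs, scale = vsc)
    }
  }
  params$value_shift <- value_std$shift
  params$value_scale <- value_std$scale
  ys <- (y - params$value_shift) / params$value_scale
  ts <- standardize_points(tc, params)

  s2 <- spec$signal_variance
  K <- kernel_matrix(os, os, spec)
  diag(K) <- diag(K) + spec$noise_variance
  fac <- .chol_psd(K, s2, jitter0 = jitter)
  rm(K)
  alpha <- backsolve(fac$R, backsolve(fac$R, ys, transpose = TRUE))
  if (spec$noise_variance == 0) {
    # with zero observation noise the jitter is pure regularization bias;
    # two steps of iterative refinement against the unjittered system keep
    # the exact-interpolation property to solver precision
    for (it in 1:2) {
      resid <- ys - .kernel_matvec(os, spec, alpha)
      alpha <- alpha + backsolve(fac$R, backsolve(fac$R, resid,
                                                  transpose = TRUE))
    }
  }
  # chunk the targets so large problems never hold more than one block of
  # cross-covariances in memory
  n_t <- nrow(ts)
  chunk <- max(1L, min(n_t, floor(2e7 / nrow(os))))
  mean_std <- numeric(n_t)
  var_std <- numeric(n_t)
  for (j0 in seq(1L, n_t, by = chunk)) {
    jj <- j0:min(j0 + chunk - 1L, n_t)
    Ks <- kernel_matrix(os, ts[jj, , drop = FALSE], spec)
    mean_std[jj] <- drop(crossprod(Ks, alpha))
    if (compute_variance) {
      V <- backsolve(fac$R, Ks, transpose = TRUE)
      var_std[jj] <- s2 - colSums(V^2)
    }
  }
  if (compute_variance) {
    if (any(var_std < -1e-8 * s2))
      stop("posterior variance fell below the floating-point tolerance")
    var_std <- pmax(var_std, 0)
  }
  structure(list(mean = destandardize_values(mean_std, params),
                 variance = if (compute_variance)
                   var_std * params$value_scale^2 else NULL,
                 diagnostics = list(jitter = fac$jitter,
                                    min_pivot = fac$min_pivot)),
            class = "gp_posterior")
}

#' @export
print.gp_posterior <- function(x, ...) {
  cat(sprintf("<gp_posterior> %d targets, mean range [%.4g, %.4g], max variance %.4g\n",
              length(x$mean), min(x$mean), max(x$mean), max(x$variance)))
  invisible(x)
}

#' Log marginal likelihood of the observations
#'
#' `log p(y | X) = -1/2 y^T (K + sigma_n^2 I)^-1 y
#'                 - 1/2 log det(K + sigma_n^2 I) - N/2 log(2 pi)`,
#' evaluated in standardized space via the Cholesky log-determinant.  This is
#' the usual GP model-selection objective; the package's length-scale fitting
#' optimizes held-out MSE instead, and this quantity is exposed as a
#' diagnostic.
#'
#' @inheritParams gp_predict
#' @return scalar log marginal likelihood.
#' @export
log_marginal_likelihood <- function(obs_coords, obs_values, spec,
                                    coord_std = NULL, jitter = 1e-10) {
  stopifnot(inherits(spec, "kernel_spec"))
  oc <- .coords_matrix(obs_coords)
  y <- as.numeric(obs_values)
  if (length(y) < 1L) stop("at least one observation is required")
  if (is.null(coord_std)) {
    std <- standardize(y, oc)
    ys <- std$values; os <- std$coords
  } else {
    os <- standardize_points(oc, coord_std)
    vs <- mean(y); vsc <- stats::sd(y)
    if (!is.finite(vsc) || vsc == 0) vsc <- 1
    ys <- (y - vs) / vsc
  }
  K <- kernel_matrix(os, os, spec)
  diag(K) <- diag(K) + spec$noise_variance
  fac <- .chol_psd(K, spec$signal_variance, jitter0 = jitter)
  alpha <- backsolve(fac$R, backsolve(fac$R, ys, transpose = TRUE))
  ll <- -0.5 * sum(ys * alpha) - sum(log(diag(fac$R))) -
    length(ys) / 2 * log(2 * pi)
  if (!is.finite(ll)) stop("log marginal likelihood is not finite")
  ll
}
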