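# Reference interpolators for head-to-head comparison with the GP.
#
# All three operate on the beam-native lattice (for diverging grids that is
# the polar grid, the standard practice for scan conversion: interpolate in
# polar coordinates, then merely remap for Cartesian display).  The sample
# axis is always uniform; the beam axis may be uneven (decimated grids carry
# explicit beam coordinates).

#' Interpolation results
#'
#' Container for the output of any interpolator: raw (unclipped) values at
#' the target points, an optional posterior variance vector (GP only), the
#' method tag and bookkeeping flags.  Metrics use the raw values so that
#' spline overshoot is not masked; [clip_values()] gives the `[0, 1]`-clipped
#' copy used for display.
#'
#' @param values numeric vector of interpolated intensities (raw).
#' @param variance optional numeric vector of posterior variances.
#' @param method method tag, e.g. `"nearest"`, `"bilinear"`, `"spline"`,
#'   `"gp"`.
#' @param outside optional logical vector flagging targets outside the
#'   observation hull (clamped-to-edge, not dropped).
#' @param fingerprint free-form provenance string.
#' @return object of class `"interpolation_result"`.
#' @export
interpolation_result <- function(values, variance = NULL, method = "unknown",
                                 outside = NULL, fingerprint = "") {
  values <- as.numeric(values)
  if (!is.null(variance)) {
    variance <- as.numeric(variance)
    stopifnot(length(variance) == length(values), all(variance >= 0))
  }
  structure(list(values = values, variance = variance, method = method,
                 outside = outside,
                 overshoot = any(values < 0 | values > 1),
                 fingerprint = fingerprint),
            class = "interpolation_result")
}

#' @export
print.interpolation_result <- function(x, ...) {
  cat(sprintf("<interpolation_result> %s, %d targets, range [%.4g, %.4g]%s\n",
              x$method, length(x$values), min(x$values), max(x$values),
              if (isTRUE(x$overshoot)) " (overshoots [0,1])" else ""))
  invisible(x)
}

#' @rdname interpolation_result
#' @param x an `"interpolation_result"`.
#' @return `clip_values()`: the values clipped to `[0, 1]`.
#' @export
clip_values <- function(x) {
  pmin(pmax(x$values, 0), 1)
}

# fractional sample index of target depths (1-based; uniform axis)
.frac_sample_index <- function(grid, r) {
  (r - grid$depth_offset) / grid$sample_pitch + 1
}

#' Nearest-neighbour interpolation
#'
#' Each target takes the value of the nearest observation in beam-native
#' coordinates, axis by axis.  Ties are broken deterministically toward the
#' lower sample index, then the lower beam index.
#'
#' @param frame a [scan_frame()].
#' @param targets a [point_set()] in the beam-native frame.
#' @return an `"interpolation_result"` with `method = "nearest"`.
#' @export
interp_nearest <- function(frame, targets) {
  stopifnot(inherits(frame, "scan_frame"))
  tc <- .coords_matrix(targets)
  g <- frame$grid
  fi <- .frac_sample_index(g, tc[, 1])
  i <- pmin(pmax(ceiling(fi - 0.5), 1L), g$n_samples)   # half-ties to lower
  b <- beam_positions(g)
  j <- .nearest_beam(tc[, 2], b)
  out_flag <- fi < 1 - 1e-12 | fi > g$n_samples + 1e-12 |
    tc[, 2] < b[1] - 1e-12 | tc[, 2] > b[length(b)] + 1e-12
  vals <- frame$intensities[cbind(i, j)]
  interpolation_result(vals, method = "nearest", outside = out_flag)
}

# index of nearest beam; ties toward the lower index (uneven-safe)
.nearest_beam <- function(a, b) {
  k <- findInterval(a, b, all.inside = TRUE)
  dl <- a - b[k]
  dr <- b[k + 1] - a
  j <- ifelse(dr < dl, k + 1L, k)     # tie (dr == dl) stays at lower k
  pmin(pmax(j, 1L), length(b))
}

#' Bilinear interpolation
#'
#' Separable linear interpolation on the beam-native lattice.  Targets
#' outside the observation hull are clamped to the edge and flagged in the
#' result's `outside` field.
#'
#' @inheritParams interp_nearest
#' @return an `"interpolation_result"` with `method = "bilinear"`.
#' @export
interp_bilinear <- function(frame, targets) {
  stopifnot(inherits(frame, "scan_frame"))
  tc <- .coords_matrix(targets)
  g <- frame$grid
  Z <- frame$intensities
  b <- beam_positions(g)
  fi <- .frac_sample_index(g, tc[, 1])
  out_flag <- fi < 1 - 1e-12 | fi > g$n_samples + 1e-12 |
    tc[, 2] < b[1] - 1e-12 | tc[, 2] > b[length(b)] + 1e-12
  fi <- pmin(pmax(fi, 1), g$n_samples)
  i0 <- pmin(floor(fi), g$n_samples - 1L)
  wi <- fi - i0
  a <- pmin(pmax(tc[, 2], b[1]), b[length(b)])
  j0 <- pmin(findInterval(a, b, all.inside = TRUE), length(b) - 1L)
  wj <- (a - b[j0]) / (b[j0 + 1] - b[j0])
  vals <- (1 - wi) * (1 - wj) * Z[cbind(i0, j0)] +
    wi * (1 - wj) * Z[cbind(i0 + 1L, j0)] +
    (1 - wi) * wj * Z[cbind(i0, j0 + 1L)] +
    wi * wj * Z[cbind(i0 + 1L, j0 + 1L)]
  interpolation_result(vals, method = "bilinear", outside = out_flag)
}

#' Separable cubic-spline interpolation
#'
#' Tensor-product cubic spline on the beam-native lattice, evaluated in two
#' passes: across beams at each sample row for the distinct target beam
#' coordinates, then along the (uniform) sample axis.  End conditions are the
#' Forsythe-Malcolm-Moler ones of [stats::spline()] (an exact cubic through
#' the four points at each end), which reproduce cubic polynomials exactly.
#' Values may overshoot `[0, 1]` near edges (Gibbs-type behaviour); raw
#' values are retained and the result is flagged.
#'
#' @inheritParams interp_nearest
#' @return an `"interpolation_result"` with `method = "spline"`.
#' @export
interp_cubic_spline <- function(frame, targets) {
  stopifnot(inherits(frame, "scan_frame"))
  g <- frame$grid
  if (g$n_samples < 4L || g$n_scanlines < 4L)
    stop("cubic spline interpolation needs at least 4 samples and 4 beams")
  tc <- .coords_matrix(targets)
  Z <- frame$intensities
  b <- beam_positions(g)
  r <- sample_depths(g)
  fi <- .frac_sample_index(g, tc[, 1])
  out_flag <- fi < 1 - 1e-12 | fi > g$n_samples + 1e-12 |
    tc[, 2] < b[1] - 1e-12 | tc[, 2] > b[length(b)] + 1e-12

  ua <- sort(unique(tc[, 2]))
  ja <- match(tc[, 2], ua)
  # pass 1: across beams, all sample rows at once per distinct target beam pos
  A <- matrix(0, g$n_samples, length(ua))
  for (s in seq_len(g$n_samples))
    A[s, ] <- stats::spline(b, Z[s, ], xout = ua, method = "fmm")$y
  # pass 2: along the sample axis within each distinct beam position
  vals <- numeric(nrow(tc))
  for (k in seq_along(ua)) {
    sel <- which(ja == k)
    on_node <- length(sel) == g$n_samples &&
      isTRUE(all.equal(tc[sel, 1], r, tolerance = 1e-12))
    vals[sel] <- if (on_node) A[, k]
    else stats::spline(r, A[, k], xout = tc[sel, 1], method = "fmm")$y
  }
  interpolation_result(vals, method = "spline", outside = out_flag)
}
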