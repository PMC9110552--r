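# Leave-N-out evaluation: withhold scanlines, interpolate from the rest,
# score against the withheld lines.  Treating the acquired scanlines as
# ground truth sidesteps the absence of a denser reference image.

#' Decimate a frame to a subset of its scanlines
#'
#' Keeps `n_keep` scanlines spaced as evenly as integer indices allow, always
#' including the first and last beam, and returns the reduced frame on its own
#' coarser grid (with explicit, possibly uneven, beam coordinates) together
#' with the held-out beam indices.  Deterministic.  The reduction factor
#' `k_N = n_scanlines / n_keep` is recorded; it is the factor by which the
#' along-beam length-scale heuristic is scaled.
#'
#' @param frame a [scan_frame()].
#' @param n_keep number of scanlines to keep (2 to `n_scanlines`).
#' @return list with `frame` (decimated [scan_frame()]), `kept` and
#'   `held_out` (1-based beam indices into the parent grid), and `k_N`.
#' @export
decimate <- function(frame, n_keep) {
  stopifnot(inherits(frame, "scan_frame"))
  g <- frame$grid
  n <- g$n_scanlines
  n_keep <- as.integer(n_keep)
  if (n_keep < 2L || n_keep > n)
    stop(sprintf("`n_keep` must be between 2 and %d", n))
  kept <- .even_subset(n, n_keep)
  b <- beam_positions(g)[kept]
  grid2 <- scan_grid(geometry = g$geometry, n_scanlines = n_keep,
                     n_samples = g$n_samples, sample_pitch = g$sample_pitch,
                     beam_pitch = if (n_keep > 1) mean(diff(b)) else g$beam_pitch,
                     depth_offset = if (g$geometry == "diverging")
                       g$depth_offset else NULL,
                     sector_center = g$sector_center,
                     beam_coords = b)
  list(frame = scan_frame(grid2, frame$intensities[, kept, drop = FALSE],
                          provenance = paste0(frame$provenance,
                                              " [decimated ", n_keep, "/", n, "]")),
       kept = kept, held_out = setdiff(seq_len(n), kept),
       k_N = n / n_keep)
}

# n_keep evenly spaced integer indices in 1..n including 1 and n
.even_subset <- function(n, n_keep) {
  if (n_keep == n) return(seq_len(n))
  idx <- round(seq(1, n, length.out = n_keep))
  for (k in seq_along(idx)[-1])            # repair any collisions forward
    if (idx[k] <= idx[k - 1]) idx[k] <- idx[k - 1] + 1L
  for (k in rev(seq_along(idx)[-n_keep]))  # and keep the tail inside 1..n
    if (idx[k] >= idx[k + 1]) idx[k] <- idx[k + 1] - 1L
  as.integer(idx)
}

.metric_args <- function(truth, est, mask) {
  truth <- as.numeric(truth); est <- as.numeric(est)
  if (length(truth) != length(est))
    stop("`truth` and `est` must have matching shapes")
  if (is.null(mask)) mask <- rep(TRUE, length(truth))
  mask <- as.logical(mask)
  if (length(mask) != length(truth))
    stop("`mask` must match the image shape")
  if (!any(mask)) stop("empty mask: no pixels to score")
  list(t = truth[mask], e = est[mask])
}

#' Image-error metrics
#'
#' `mae()` is the mean absolute difference, `mse()` the mean squared
#' difference, and `psnr()` the peak signal-to-noise ratio
#' `10 log10(1 / MSE)` in dB, for intensities normalized to `[0, 1]`.
#' All three score only unmasked pixels.  Identical images give
#' `psnr() = Inf`, the documented sentinel.
#'
#' @param truth,est numeric vectors/matrices of matching shape.
#' @param mask optional logical vector/matrix selecting the scored pixels.
#' @return scalar metric value.
#' @export
mae <- function(truth, est, mask = NULL) {
  a <- .metric_args(truth, est, mask)
  mean(abs(a$t - a$e))
}

#' @rdname mae
#' @export
mse <- function(truth, est, mask = NULL) {
  a <- .metric_args(truth, est, mask)
  mean((a$t - a$e)^2)
}

#' @rdname mae
#' @export
psnr <- function(truth, est, mask = NULL) {
  m <- mse(truth, est, mask)
  if (m == 0) return(Inf)
  10 * log10(1 / m)
}

#' Leave-N-out interpolation study
#'
#' For every combination of method and keep count: decimates the frame,
#' interpolates back onto the full observation lattice in the beam-native
#' frame, and scores against the held-out scanlines only (kept-scanline
#' pixels never enter the error sums; interpolators are exact there, so
#' whole-image scores would dilute the differences).  GP cells additionally
#' record the mean posterior variance.  Relative PSNR is computed per keep
#' count by subtracting the column's lowest score, so the worst method sits
#' at exactly 0 in every column.
#'
#' When `n_keep` equals the full scanline count there are no held-out beams
#' and the degenerate cell is scored over the whole lattice (interpolating
#' methods then hit the `Inf` PSNR sentinel).
#'
#' @param frame a [scan_frame()] (ground truth).
#' @param methods character subset of
#'   `c("nearest", "bilinear", "spline", "gp")`.
#' @param keep_counts integer vector of scanline counts to keep.
#' @param spec a [kernel_spec()] for the GP method; when `scales =
#'   "heuristic"` only its family, `nu`, `sigma^2` and `sigma_n^2` are used
#'   and the length scales are set per cell from [heuristic_length_scales()]
#'   with that cell's reduction factor.  Defaults to Matern 3/2 with the
#'   geometry's default noise.
#' @param window_size GP window size (observations per patch window).
#' @param scales `"heuristic"` (default) or `"as_given"` (use `spec`'s
#'   length scales, standardized units, at every cell).
#' @param targets_per_patch passed to [plan_patches()].
#' @return an `"evaluation_report"`: a long-format `data.frame` with columns
#'   `method`, `n_keep`, `psnr_db`, `mae`, `mse`, `rel_psnr_db`,
#'   `mean_variance`.
#' @export
leave_n_out_study <- function(frame,
                              methods = c("nearest", "bilinear", "spline", "gp"),
                              keep_counts, spec = NULL, window_size = 15L,
                              scales = c("heuristic", "as_given"),
                              targets_per_patch = 8L) {
  stopifnot(inherits(frame, "scan_frame"))
  scales <- match.arg(scales)
  methods <- match.arg(methods, several.ok = TRUE)
  g <- frame$grid
  if (is.null(spec))
    spec <- kernel_spec("matern", nu = 1.5, signal_variance = 1,
                        length_scale_r = 1, length_scale_alpha = 1,
                        noise_variance = default_noise_variance(g$geometry))
  full_obs <- observation_coords(g)
  rows <- list()
  for (n_keep in as.integer(keep_counts)) {
    dec <- decimate(frame, n_keep)
    ho <- dec$held_out
    if (length(ho) > 0L) {
      idx <- as.vector(outer(seq_len(g$n_samples),
                             (ho - 1L) * g$n_samples, "+"))
      targets <- full_obs[idx]
      truth <- as.vector(frame$intensities[, ho, drop = FALSE])
    } else {
      targets <- full_obs
      truth <- as.vector(frame$intensities)
    }
    gp_bits <- NULL
    for (method in methods) {
      cell <- tryCatch({
        res <- switch(method,
          nearest = interp_nearest(dec$frame, targets),
          bilinear = interp_bilinear(dec$frame, targets),
          spline = interp_cubic_spline(dec$frame, targets),
          gp = {
            if (is.null(gp_bits)) {
              spec_use <- .study_spec(spec, dec$frame$grid, dec$k_N, scales)
              plan <- plan_patches(dec$frame$grid, targets,
                                   window_size = window_size,
                                   targets_per_patch = targets_per_patch,
                                   metric_scales =
                                     c(spec_use$length_scale_r,
                                       spec_use$length_scale_alpha))
              ops <- build_operators(plan, dec$frame$grid, spec_use)
              gp_bits <- list(plan = plan, ops = ops)
            }
            patched_predict(gp_bits$ops, dec$frame, gp_bits$plan)
          })
        data.frame(method = method, n_keep = n_keep,
                   psnr_db = psnr(truth, res$values),
                   mae = mae(truth, res$values),
                   mse = mse(truth, res$values),
                   mean_variance = if (is.null(res$variance)) NA_real_
                                   else mean(res$variance))
      }, error = function(e) {
        warning(sprintf("method %s at n_keep %d failed: %s",
                        method, n_keep, conditionMessage(e)))
        data.frame(method = method, n_keep = n_keep, psnr_db = NA_real_,
                   mae = NA_real_, mse = NA_real_, mean_variance = NA_real_)
      })
      rows[[length(rows) + 1L]] <- cell
    }
  }
  rep <- do.call(rbind, rows)
  rep$rel_psnr_db <- NA_real_
  for (n_keep in unique(rep$n_keep)) {
    sel <- rep$n_keep == n_keep & is.finite(rep$psnr_db)
    if (any(sel))
      rep$rel_psnr_db[rep$n_keep == n_keep] <-
        rep$psnr_db[rep$n_keep == n_keep] - min(rep$psnr_db[sel])
  }
  rep <- rep[, c("method", "n_keep", "psnr_db", "mae", "mse",
                 "rel_psnr_db", "mean_variance")]
  class(rep) <- c("evaluation_report", "data.frame")
  attr(rep, "window_size") <- window_size
  attr(rep, "scales") <- scales
  rep
}

# per-cell GP spec: heuristic length scales in standardized units of the
# decimated grid, or the user's spec as given
.study_spec <- function(spec, dec_grid, k_N, scales) {
  if (scales == "as_given") return(spec)
  std <- grid_std_params(dec_grid)
  h <- heuristic_length_scales(dec_grid, k_N = k_N,
                               depth = if (dec_grid$geometry == "diverging")
                                 scanline_length(dec_grid) / 2 else NULL,
                               std = std)
  kernel_spec(spec$family, nu = if (is.na(spec$nu)) 1.5 else spec$nu,
              signal_variance = spec$signal_variance,
              length_scale_r = h[["l_r"]], length_scale_alpha = h[["l_alpha"]],
              noise_variance = spec$noise_variance)
}

#' Default observation-noise variance by geometry
#'
#' The operating points used throughout: `2e-3` for parallel (linear-probe)
#' grids and `8e-3` for diverging (phased-array) grids, in standardized
#' intensity units.
#'
#' @param geometry `"parallel"` or `"diverging"`.
#' @return numeric scalar.
#' @export
default_noise_variance <- function(geometry = c("parallel", "diverging")) {
  geometry <- match.arg(geometry)
  if (geometry == "parallel") 2e-3 else 8e-3
}

#' Normalize a set of variance maps jointly
#'
#' Divides every map by the single global maximum across the whole set, so
#' that maps from different decimation levels remain comparable (darker =
#' more confident).  An all-zero set is returned unchanged with a flag.
#'
#' @param maps list of numeric matrices/vectors of posterior variances.
#' @return list of maps scaled into `[0, 1]`; attribute `all_zero` flags the
#'   degenerate case, attribute `coefficient` records the divisor.
#' @export
normalize_variance_maps <- function(maps) {
  if (!is.list(maps)) maps <- list(maps)
  if (length(maps) < 1L) stop("at least one variance map is required")
  mx <- max(vapply(maps, function(m) max(as.numeric(m)), numeric(1)))
  if (mx <= 0)
    return(structure(maps, all_zero = TRUE, coefficient = 1))
  structure(lapply(maps, function(m) m / mx), all_zero = FALSE,
            coefficient = mx)
}
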