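#' Scanline lattice geometry
#'
#' A `scan_grid` describes the lattice on which beamformed scanline samples
#' live.  Linear-array probes emit parallel beams, so the lattice is Cartesian:
#' the across-beam coordinate is a lateral offset in length units.  Phased and
#' curvilinear probes emit beams diverging from an apex, so the lattice is
#' polar: the across-beam coordinate is the beam angle in radians and samples
#' along a beam are depths from the apex.
#'
#' The beam-native frame used throughout the package puts the along-beam
#' (radial) coordinate first and the across-beam (lateral or angular)
#' coordinate second.  Sample `i` (1-based) lies at depth
#' `depth_offset + (i - 1) * sample_pitch`; beams are centred so that the
#' middle beam sits at `sector_center` (diverging) or at zero lateral offset
#' (parallel).
#'
#' @param geometry `"parallel"` or `"diverging"`.
#' @param n_scanlines number of beams (>= 2).
#' @param n_samples number of samples per beam (>= 2).
#' @param sample_pitch spacing between samples along a beam (length units, > 0).
#' @param beam_pitch spacing between beams: a lateral length for parallel
#'   grids, an angular step in radians for diverging grids (> 0).
#' @param depth_offset distance from the apex to the first sample (diverging
#'   grids; defaults to `sample_pitch` so that no sample sits at the apex
#'   singularity of the 1/r length-scale rule).  Ignored (zero) for parallel
#'   grids.
#' @param sector_center angle of the middle beam in radians (diverging grids).
#' @param beam_coords optional explicit across-beam coordinates, one per beam,
#'   strictly increasing.  Used for grids whose beams are not evenly spaced,
#'   e.g. the output of [decimate()].  When given, `beam_pitch` is only used
#'   as the nominal spacing.
#' @return An object of class `"scan_grid"`.
#' @seealso [observation_coords()], [scan_frame()], [decimate()]
#' @examples
#' g <- scan_grid("diverging", n_scanlines = 64, n_samples = 412,
#'                sample_pitch = 1, beam_pitch = pi / 2 / 63)
#' scanline_length(g)
#' @export
scan_grid <- function(geometry = c("parallel", "diverging"),
                      n_scanlines, n_samples,
                      sample_pitch = 1, beam_pitch,
                      depth_offset = NULL, sector_center = 0,
                      beam_coords = NULL) {
  geometry <- match.arg(geometry)
  stopifnot(length(n_scanlines) == 1, length(n_samples) == 1)
  n_scanlines <- as.integer(n_scanlines)
  n_samples <- as.integer(n_samples)
  if (n_scanlines < 2L) stop("`n_scanlines` must be >= 2")
  if (n_samples < 2L) stop("`n_samples` must be >= 2")
  if (!is.finite(sample_pitch) || sample_pitch <= 0)
    stop("`sample_pitch` must be > 0")
  if (!is.finite(beam_pitch) || beam_pitch <= 0)
    stop("`beam_pitch` must be > 0")
  if (geometry == "diverging") {
    if ((n_scanlines - 1) * beam_pitch >= pi)
      stop("total sector angle (n_scanlines - 1) * beam_pitch must be < pi")
    if (is.null(depth_offset)) depth_offset <- sample_pitch
    if (!is.finite(depth_offset) || depth_offset < 0)
      stop("`depth_offset` must be >= 0")
  } else {
    depth_offset <- 0
    sector_center <- 0
  }
  if (!is.null(beam_coords)) {
    beam_coords <- as.numeric(beam_coords)
    if (length(beam_coords) != n_scanlines)
      stop("`beam_coords` must have one entry per scanline")
    if (any(!is.finite(beam_coords)) || any(diff(beam_coords) <= 0))
      stop("`beam_coords` must be finite and strictly increasing")
  }
  structure(
    list(geometry = geometry,
         n_scanlines = n_scanlines, n_samples = n_samples,
         sample_pitch = sample_pitch, beam_pitch = beam_pitch,
         depth_offset = depth_offset, sector_center = sector_center,
         beam_coords = beam_coords),
    class = "scan_grid")
}

#' @export
print.scan_grid <- function(x, ...) {
  cat(sprintf("<scan_grid> %s, %d scanlines x %d samples\n",
              x$geometry, x$n_scanlines, x$n_samples))
  cat(sprintf("  sample_pitch %g, beam_pitch %g%s\n", x$sample_pitch,
              x$beam_pitch, if (x$geometry == "diverging") " rad" else ""))
  if (x$geometry == "diverging")
    cat(sprintf("  depth_offset %g, sector_center %g rad\n",
                x$depth_offset, x$sector_center))
  if (!is.null(x$beam_coords)) cat("  explicit (uneven) beam coordinates\n")
  invisible(x)
}

#' Scanline length, sample depths and beam positions
#'
#' `scanline_length()` returns the along-beam extent
#' `(n_samples - 1) * sample_pitch`.  `sample_depths()` returns the along-beam
#' coordinate of every sample; `beam_positions()` the across-beam coordinate of
#' every beam (centred as described in [scan_grid()]).
#'
#' @param grid a [scan_grid()].
#' @return numeric scalar / vector.
#' @export
scanline_length <- function(grid) {
  stopifnot(inherits(grid, "scan_grid"))
  (grid$n_samples - 1) * grid$sample_pitch
}

#' @rdname scanline_length
#' @export
sample_depths <- function(grid) {
  stopifnot(inherits(grid, "scan_grid"))
  grid$depth_offset + (seq_len(grid$n_samples) - 1) * grid$sample_pitch
}

#' @rdname scanline_length
#' @export
beam_positions <- function(grid) {
  stopifnot(inherits(grid, "scan_grid"))
  if (!is.null(grid$beam_coords)) return(grid$beam_coords)
  center <- if (grid$geometry == "diverging") grid$sector_center else 0
  center + ((seq_len(grid$n_scanlines) - 1) - (grid$n_scanlines - 1) / 2) *
    grid$beam_pitch
}

#' Point sets in beam-native or Cartesian coordinates
#'
#' A `point_set` is an M x 2 matrix of coordinates.  Column 1 is the
#' along-beam (radial) coordinate, column 2 the across-beam (lateral or
#' angular) coordinate when `frame = "beam_native"`; for
#' `frame = "cartesian"` the columns are lateral x and axial z.
#'
#' @param coords numeric M x 2 matrix (or a length-2 vector for one point).
#' @param frame `"beam_native"` or `"cartesian"`.
#' @param outside optional logical vector flagging points outside the probe
#'   footprint (kept, never dropped).
#' @return matrix with class `"point_set"` and attributes `frame`, `outside`.
#' @export
point_set <- function(coords, frame = c("beam_native", "cartesian"),
                      outside = NULL) {
  frame <- match.arg(frame)
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 2)
  coords <- as.matrix(coords)
  if (ncol(coords) != 2) stop("`coords` must have two columns")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  storage.mode(coords) <- "double"
  if (!is.null(outside)) {
    outside <- as.logical(outside)
    if (length(outside) != nrow(coords))
      stop("`outside` must flag every point")
  }
  structure(coords, frame = frame, outside = outside, class = "point_set")
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("<point_set> %d points, frame = %s\n", nrow(x), attr(x, "frame")))
  if (!is.null(attr(x, "outside")))
    cat(sprintf("  %d flagged outside the footprint\n", sum(attr(x, "outside"))))
  invisible(x)
}

# row subsets keep the class and attributes; column access behaves like a
# plain matrix
#' @export
`[.point_set` <- function(x, i, j, ..., drop) {
  out <- attr(x, "outside")
  m <- unclass(x)
  if (missing(j) && nargs() < 3L) {
    r <- m[i, , drop = FALSE]
    return(point_set(r, frame = attr(x, "frame"),
                     outside = if (!is.null(out)) out[i] else NULL))
  }
  if (missing(drop)) m[i, j] else m[i, j, drop = drop]
}

#' Observation lattice coordinates
#'
#' Returns the beam-native coordinates of every sample of a scanline grid, in
#' a fixed documented order: the sample index runs fastest, so the k-th point
#' corresponds to entry `intensities[i, j]` with `k = (j - 1) * n_samples + i`
#' (i.e. `as.vector()` of the intensity matrix).
#'
#' @param grid a [scan_grid()].
#' @return a [point_set()] of `n_samples * n_scanlines` rows in the
#'   beam-native frame.
#' @export
observation_coords <- function(grid) {
  stopifnot(inherits(grid, "scan_grid"))
  r <- sample_depths(grid)
  a <- beam_positions(grid)
  point_set(cbind(rep(r, times = grid$n_scanlines),
                  rep(a, each = grid$n_samples)),
            frame = "beam_native")
}

#' Interpolation target coordinates
#'
#' Builds the set of points at which a frame is to be interpolated.
#' `"native_dense"` refines the beam-native lattice by an integer factor per
#' axis (density 1 reproduces [observation_coords()] exactly); this is the
#' lattice used by leave-N-out studies, which score held-out scanlines in the
#' beam-native frame.  `"cartesian_raster"` returns display raster pixel
#' centres mapped into beam-native coordinates; pixels outside the probe
#' footprint are flagged via the `outside` attribute, never dropped.
#'
#' @param grid a [scan_grid()].
#' @param target `"native_dense"` or `"cartesian_raster"`.
#' @param density integer refinement factor per axis for `"native_dense"`.
#' @param pixel_spacing raster pixel size (same length units as
#'   `sample_pitch`) for `"cartesian_raster"`; defaults to `sample_pitch`.
#' @param bbox optional raster bounding box `c(x_min, x_max, z_min, z_max)`;
#'   defaults to the grid footprint.
#' @return a [point_set()] in the beam-native frame.  For rasters the
#'   Cartesian pixel centres are kept in attribute `cartesian` and the raster
#'   dimensions in attribute `raster_dim` (`c(n_z, n_x)`).
#' @export
interpolation_coords <- function(grid,
                                 target = c("native_dense", "cartesian_raster"),
                                 density = 1L,
                                 pixel_spacing = NULL, bbox = NULL) {
  stopifnot(inherits(grid, "scan_grid"))
  target <- match.arg(target)
  if (target == "native_dense") {
    density <- as.integer(density)
    if (density < 1L) stop("`density` must be a positive integer")
    r <- sample_depths(grid)
    a <- beam_positions(grid)
    rr <- .refine_axis(r, density)
    aa <- .refine_axis(a, density)
    return(point_set(cbind(rep(rr, times = length(aa)),
                           rep(aa, each = length(rr))),
                     frame = "beam_native"))
  }
  # cartesian raster over the footprint
  if (is.null(pixel_spacing)) pixel_spacing <- grid$sample_pitch
  if (pixel_spacing <= 0) stop("`pixel_spacing` must be > 0")
  fp <- .grid_footprint(grid)
  if (is.null(bbox)) bbox <- fp
  x <- seq(bbox[1] + pixel_spacing / 2, bbox[2], by = pixel_spacing)
  z <- seq(bbox[3] + pixel_spacing / 2, bbox[4], by = pixel_spacing)
  if (length(x) == 0 || length(z) == 0)
    stop("raster bounding box does not intersect the probe footprint")
  xy <- cbind(rep(x, each = length(z)), rep(z, times = length(x)))
  cart <- point_set(xy, frame = "cartesian")
  bn <- cartesian_to_polar(cart, grid)
  r <- bn[, 1]; a <- bn[, 2]
  rng_r <- range(sample_depths(grid)); rng_a <- range(beam_positions(grid))
  eps <- 1e-9
  outside <- r < rng_r[1] - eps | r > rng_r[2] + eps |
    a < rng_a[1] - eps | a > rng_a[2] + eps
  if (all(outside))
    stop("raster bounding box does not intersect the probe footprint")
  structure(point_set(unclass(bn), frame = "beam_native", outside = outside),
            cartesian = xy, raster_dim = c(length(z), length(x)),
            class = "point_set")
}

.refine_axis <- function(v, density) {
  if (density == 1L) return(v)
  n <- length(v)
  out <- stats::approx(seq_len(n), v,
                       xout = seq(1, n, by = 1 / density))$y
  out
}

# Cartesian bounding box of the imaged region: x lateral, z axial (depth).
.grid_footprint <- function(grid) {
  r <- range(sample_depths(grid))
  a <- range(beam_positions(grid))
  if (grid$geometry == "parallel") return(c(a[1], a[2], r[1], r[2]))
  rel <- a - grid$sector_center
  x <- c(r[1] * sin(rel[1]), r[2] * sin(rel[1]),
         r[1] * sin(rel[2]), r[2] * sin(rel[2]), 0)
  th_max <- max(abs(rel))
  z <- c(r[1] * cos(th_max), r[2])             # min z on edge beams, max on axis
  if (rel[1] <= 0 && rel[2] >= 0) z[2] <- r[2] # axis inside sector
  c(min(x), max(x), min(z), max(z))
}

#' Convert between beam-native (polar) and Cartesian frames
#'
#' For diverging grids the map is the standard polar one with the sector
#' centre on the +z axis: `x = r * sin(alpha - sector_center)`,
#' `z = r * cos(alpha - sector_center)`.  For parallel grids the beam-native
#' frame already is Cartesian (r -> z, lateral -> x), so the map just swaps
#' columns; applying it is documented as the identity on the geometry.
#'
#' @param points a [point_set()].
#' @param grid the [scan_grid()] the points were generated from.
#' @return a [point_set()] in the other frame; `outside` flags are preserved.
#' @export
polar_to_cartesian <- function(points, grid) {
  stopifnot(inherits(points, "point_set"), inherits(grid, "scan_grid"))
  if (attr(points, "frame") != "beam_native")
    stop("`points` must be in the beam_native frame")
  out <- attr(points, "outside")
  if (grid$geometry == "parallel")
    return(point_set(cbind(points[, 2], points[, 1]), "cartesian", out))
  th <- points[, 2] - grid$sector_center
  point_set(cbind(points[, 1] * sin(th), points[, 1] * cos(th)),
            "cartesian", out)
}

#' @rdname polar_to_cartesian
#' @export
cartesian_to_polar <- function(points, grid) {
  stopifnot(inherits(points, "point_set"), inherits(grid, "scan_grid"))
  if (attr(points, "frame") != "cartesian")
    stop("`points` must be in the cartesian frame")
  out <- attr(points, "outside")
  if (grid$geometry == "parallel")
    return(point_set(cbind(points[, 2], points[, 1]), "beam_native", out))
  x <- points[, 1]; z <- points[, 2]
  r <- sqrt(x^2 + z^2)
  a <- grid$sector_center + atan2(x, z)
  a[r == 0] <- grid$sector_center  # apex: angle undefined, pick the axis
  point_set(cbind(r, a), "beam_native", out)
}

#' Scanline frames
#'
#' A `scan_frame` couples a [scan_grid()] with its echo-intensity matrix
#' (`n_samples` rows by `n_scanlines` columns, values in `[0, 1]`).
#'
#' @param grid a [scan_grid()].
#' @param intensities numeric matrix, `n_samples x n_scanlines`, in `[0, 1]`.
#' @param provenance free-text tag recording where the frame came from.
#' @return object of class `"scan_frame"`.
#' @export
scan_frame <- function(grid, intensities, provenance = "") {
  stopifnot(inherits(grid, "scan_grid"))
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != grid$n_samples ||
      ncol(intensities) != grid$n_scanlines)
    stop(sprintf("intensity matrix is %d x %d but the grid is %d x %d",
                 nrow(intensities), ncol(intensities),
                 grid$n_samples, grid$n_scanlines))
  if (any(!is.finite(intensities)))
    stop("intensities must all be finite")
  if (min(intensities) < 0 || max(intensities) > 1)
    stop("intensities must lie within [0, 1]")
  storage.mode(intensities) <- "double"
  structure(list(grid = grid, intensities = intensities,
                 provenance = as.character(provenance)),
            class = "scan_frame")
}

#' @export
print.scan_frame <- function(x, ...) {
  cat(sprintf("<scan_frame> %s, %d scanlines x %d samples, range [%.3f, %.3f]\n",
              x$grid$geometry, x$grid$n_scanlines, x$grid$n_samples,
              min(x$intensities), max(x$intensities)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}
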