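# Frame I/O: intensity matrices as PGM (P2 ASCII or P5 binary, 8/16-bit),
# 8-bit grayscale PNG, or CSV, with the geometry in a JSON sidecar.

.sidecar_path <- function(path) paste0(path, ".json")

#' Write a scanline frame to disk
#'
#' The intensity matrix goes to `path` (format chosen by extension: `.pgm`,
#' `.png` or `.csv`), the geometry to a JSON sidecar with keys `geometry`,
#' `n_scanlines`, `n_samples`, `sample_pitch`, `beam_pitch`, `depth_offset`,
#' `sector_center` (plus `beam_coords` for uneven grids and `provenance`).
#' PGM files are written as plain-text P2 with a 16-bit range (values scaled
#' to 0..65535); PNG is 8-bit grayscale; CSV is lossless full precision.
#'
#' @param frame a [scan_frame()].
#' @param path output file path (`.pgm`, `.png` or `.csv`).
#' @param sidecar_path JSON sidecar path; defaults to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path, sidecar_path = .sidecar_path(path)) {
  stopifnot(inherits(frame, "scan_frame"))
  ext <- tolower(tools::file_ext(path))
  Z <- frame$intensities
  if (ext == "pgm") {
    q <- round(Z * 65535)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", sprintf("%d %d", ncol(q), nrow(q)), "65535"), con)
    # one image row per line; PGM rows are image rows (samples)
    write.table(q, con, row.names = FALSE, col.names = FALSE)
  } else if (ext == "png") {
    png::writePNG(Z, path)            # 8-bit grayscale
  } else if (ext == "csv") {
    utils::write.table(Z, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else stop(sprintf("unknown frame format '.%s' (use .pgm, .png or .csv)", ext))
  g <- frame$grid
  side <- list(geometry = g$geometry, n_scanlines = g$n_scanlines,
               n_samples = g$n_samples, sample_pitch = g$sample_pitch,
               beam_pitch = g$beam_pitch, depth_offset = g$depth_offset,
               sector_center = g$sector_center,
               provenance = frame$provenance)
  if (!is.null(g$beam_coords)) side$beam_coords <- g$beam_coords
  jsonlite::write_json(side, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scanline frame from disk
#'
#' Counterpart of [write_frame()].  Intensities are rescaled to `[0, 1]`
#' from the container's bit depth (PGM `maxval`, PNG bit depth; CSV is read
#' as-is) and the matrix shape is cross-checked against the sidecar.
#'
#' @param path intensity file (`.pgm`, `.png` or `.csv`).
#' @param sidecar_path JSON sidecar path; defaults to `paste0(path, ".json")`.
#' @return a [scan_frame()].
#' @export
read_frame <- function(path, sidecar_path = .sidecar_path(path)) {
  if (!file.exists(path)) stop(sprintf("frame file not found: %s", path))
  if (!file.exists(sidecar_path))
    stop(sprintf("sidecar not found: %s", sidecar_path))
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(side$geometry) ||
      !side$geometry %in% c("parallel", "diverging"))
    stop("sidecar has an unknown `geometry` (expected parallel or diverging)")
  ext <- tolower(tools::file_ext(path))
  Z <- switch(ext,
              pgm = .read_pgm(path),
              png = {
                im <- png::readPNG(path)
                if (length(dim(im)) == 3L) im <- im[, , 1]
                im
              },
              csv = as.matrix(utils::read.table(path, sep = ",",
                                                header = FALSE)),
              stop(sprintf("unknown frame format '.%s'", ext)))
  dimnames(Z) <- NULL
  if (nrow(Z) != side$n_samples || ncol(Z) != side$n_scanlines)
    stop(sprintf("shape mismatch: matrix is %d x %d but sidecar says %d x %d",
                 nrow(Z), ncol(Z), side$n_samples, side$n_scanlines))
  if (min(Z) < 0 || max(Z) > 1)
    stop("intensities out of range [0, 1] after rescaling")
  grid <- scan_grid(geometry = side$geometry,
                    n_scanlines = side$n_scanlines,
                    n_samples = side$n_samples,
                    sample_pitch = side$sample_pitch,
                    beam_pitch = side$beam_pitch,
                    depth_offset = if (side$geometry == "diverging")
                      side$depth_offset else NULL,
                    sector_center = if (!is.null(side$sector_center))
                      side$sector_center else 0,
                    beam_coords = side$beam_coords)
  scan_frame(grid, Z, provenance = if (!is.null(side$provenance))
    side$provenance else "")
}

# P2 (ASCII) and P5 (binary) PGM; returns a [0,1] matrix
.read_pgm <- function(path) {
  con <- file(path, "rb")
  magic <- readChar(con, 2L, useBytes = TRUE)
  close(con)
  if (!identical(magic, "P2") && !identical(magic, "P5"))
    stop("not a PGM file (expected P2 or P5)")
  if (magic == "P2") {
    txt <- readLines(path, warn = FALSE)
    txt <- sub("#.*$", "", txt)            # strip comments
    vals <- scan(text = txt[-1], what = numeric(), quiet = TRUE)
    if (length(vals) < 3L) stop("truncated PGM header")
    w <- vals[1]; h <- vals[2]; maxval <- vals[3]
    px <- vals[-(1:3)]
    if (length(px) != w * h) stop("truncated PGM pixel data")
    Z <- matrix(px, nrow = h, ncol = w, byrow = TRUE)
    return(Z / maxval)
  }
  # P5: parse the header byte-wise, then read binary pixel data
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 2L, useBytes = TRUE)
  head <- integer(0); buf <- character(0)
  while (length(head) < 3L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0 || !nzchar(ch)) stop("truncated PGM header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0 || ch == "\n") break
      }
    } else if (grepl("[0-9]", ch)) {
      buf <- c(buf, ch)
    } else if (length(buf) > 0) {
      head <- c(head, as.integer(paste(buf, collapse = "")))
      buf <- character(0)
    }
  }
  w <- head[1]; h <- head[2]; maxval <- head[3]
  sz <- if (maxval > 255) 2L else 1L
  raw <- readBin(con, "integer", n = w * h, size = sz, signed = FALSE,
                 endian = "big")
  if (length(raw) != w * h) stop("truncated PGM pixel data")
  Z <- matrix(raw, nrow = h, ncol = w, byrow = TRUE)
  Z / maxval
}

#' Write an interpolation result as an image and/or CSV
#'
#' Writes the `[0, 1]`-clipped mean image (and, for the GP, the variance
#' map) for a result whose targets form a lattice.
#'
#' @param result an `"interpolation_result"`.
#' @param dim `c(n_rows, n_cols)` lattice shape of the targets.
#' @param path output path (`.pgm`, `.png` or `.csv`).
#' @param what `"mean"` or `"variance"`.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, dim, path, what = c("mean", "variance")) {
  stopifnot(inherits(result, "interpolation_result"))
  what <- match.arg(what)
  v <- if (what == "mean") clip_values(result) else {
    if (is.null(result$variance)) stop("result has no variance map")
    nv <- normalize_variance_maps(list(result$variance))[[1]]
    nv
  }
  M <- matrix(v, dim[1], dim[2])
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.table(M, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else if (ext == "pgm") {
    q <- round(M * 65535)
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("P2", sprintf("%d %d", ncol(q), nrow(q)), "65535"), con)
    write.table(q, con, row.names = FALSE, col.names = FALSE)
  } else if (ext == "png") {
    png::writePNG(M, path)
  } else stop(sprintf("unknown output format '.%s'", ext))
  invisible(path)
}
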