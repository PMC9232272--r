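## Scan-protocol descriptor and core acquisition containers.
##
## Coordinate conventions (global to the package):
##   * B-scan pixels are stored depth-major: rows = z (row 1 is the
##     shallowest depth), columns = lateral position.
##   * Fast-axis B-scans sweep x (columns = x); slow-axis reference
##     B-scans sweep y (columns = y).
##   * All indices exposed in files and in the API are 0-based; depths
##     are stored in pixels and converted to micrometers only in reports.

#' Scan protocol
#'
#' Describes one motion-compensated C-scan acquisition: three (by
#' default) slow-axis reference B-scans followed by a raster C-scan of
#' `n_slow` fast-axis B-scans.  `alpha` is the ratio d/L between the
#' spacing of adjacent reference planes and the B-scan width; with an
#' odd number of references the middle plane sits at the image center.
#'
#' @param n_depth axial pixels per A-scan.
#' @param n_fast A-scans per fast-axis B-scan.
#' @param n_slow fast-axis B-scans per C-scan.
#' @param axial_pitch_um axial micrometers per pixel (3.6 for corneal
#'   tissue: a 3.7 mm depth range over 1024 pixels).
#' @param fast_pitch_um lateral micrometers per pixel along x.
#' @param slow_pitch_um lateral micrometers per pixel along y.
#' @param bscan_rate_hz B-scans per second.
#' @param n_refs number of reference planes t.
#' @param alpha reference spacing ratio d/L, in (0, 0.5].
#' @param ref_positions 0-based fast-axis column indices of the
#'   reference planes; defaults to the alpha rule
#'   `mu = (1/2 - alpha, 1/2, 1/2 + alpha) * (n_fast - 1)` for three
#'   references and to the even-distribution rule `(2i-1) L / (2t)`
#'   otherwise, rounded to integer columns.
#' @return object of class `scan_protocol`.
#' @export
scan_protocol <- function(n_depth = 1024L, n_fast = 1024L, n_slow = 512L,
                          axial_pitch_um = 3.6,
                          fast_pitch_um = 10000 / 1024,
                          slow_pitch_um = 11000 / 512,
                          bscan_rate_hz = 100,
                          n_refs = 3L, alpha = 0.33,
                          ref_positions = NULL) {
  for (nm in c("n_depth", "n_fast", "n_slow"))
    if (!is_count(get(nm), 2L)) abort_oct(paste(nm, "must be an integer >= 2"), "octmoco_value")
  for (nm in c("axial_pitch_um", "fast_pitch_um", "slow_pitch_um", "bscan_rate_hz"))
    if (!is_number(get(nm)) || get(nm) <= 0) abort_oct(paste(nm, "must be > 0"), "octmoco_value")
  if (!is_count(n_refs, 2L)) abort_oct("n_refs must be an integer >= 2", "octmoco_value")
  if (!is_number(alpha) || alpha <= 0 || alpha > 0.5)
    abort_oct("alpha must be in (0, 0.5]", "octmoco_value")
  m <- n_fast - 1L
  if (is.null(ref_positions)) {
    ref_positions <- if (n_refs == 3L) {
      round(c((0.5 - alpha) * m, n_fast / 2, (0.5 + alpha) * m))
    } else {
      round(plane_positions(n_refs, n_fast) - 0.5)
    }
  }
  ref_positions <- as.integer(ref_positions)
  if (length(ref_positions) != n_refs)
    abort_oct("ref_positions length must equal n_refs", "octmoco_value")
  if (any(diff(ref_positions) <= 0))
    abort_oct("ref_positions must be strictly increasing", "octmoco_value")
  if (any(ref_positions < 0L) || any(ref_positions > m))
    abort_oct("ref_positions must lie in [0, n_fast - 1]", "octmoco_value")
  structure(list(n_depth = as.integer(n_depth), n_fast = as.integer(n_fast),
                 n_slow = as.integer(n_slow),
                 axial_pitch_um = axial_pitch_um,
                 fast_pitch_um = fast_pitch_um,
                 slow_pitch_um = slow_pitch_um,
                 bscan_rate_hz = bscan_rate_hz,
                 n_refs = as.integer(n_refs), alpha = alpha,
                 ref_positions = ref_positions),
            class = "scan_protocol")
}

#' @export
print.scan_protocol <- function(x, ...) {
  cat(sprintf("scan_protocol: %d x %d x %d voxels (Z x X x Y), %g um/px axial\n",
              x$n_depth, x$n_fast, x$n_slow, x$axial_pitch_um))
  cat(sprintf("  %d reference planes at columns [%s], alpha = %g\n",
              x$n_refs, paste(x$ref_positions, collapse = ", "), x$alpha))
  invisible(x)
}

protocol_keys <- c("n_depth", "n_fast", "n_slow", "axial_pitch_um",
                   "fast_pitch_um", "slow_pitch_um", "bscan_rate_hz",
                   "n_refs", "alpha", "ref_positions")

#' Write / read a protocol sidecar (JSON)
#'
#' The sidecar carries exactly the keys of [scan_protocol()].
#' @param protocol `scan_protocol`.
#' @param path file path.
#' @export
write_protocol_json <- function(protocol, path) {
  jsonlite::write_json(unclass(protocol), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_protocol_json
#' @export
read_protocol_json <- function(path) {
  if (!file.exists(path)) abort_oct(paste("no such file:", path), "octmoco_io")
  x <- jsonlite::fromJSON(path)
  unknown <- setdiff(names(x), protocol_keys)
  if (length(unknown))
    abort_oct(paste("unknown protocol keys:", paste(unknown, collapse = ", ")),
              "octmoco_config")
  do.call(scan_protocol, x)
}

#' Single B-scan frame
#'
#' @param pixels numeric matrix, rows = depth (z), columns = lateral.
#' @param axis_role `"fast"` or `"slow"`.
#' @param index 0-based acquisition index (the B-scan index t).
#' @param slow_position y index of a fast-axis frame, or the fast-axis
#'   column index x of a slow-axis reference.
#' @export
bscan <- function(pixels, axis_role = c("fast", "slow"), index = 0L,
                  slow_position = 0L) {
  axis_role <- match.arg(axis_role)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    abort_oct("pixels must be a numeric matrix", "octmoco_shape")
  if (any(!is.finite(pixels)))
    abort_oct("pixel intensities must be finite", "octmoco_value")
  if (index < 0) abort_oct("index must be >= 0", "octmoco_value")
  structure(list(pixels = pixels, axis_role = axis_role,
                 index = as.integer(index),
                 slow_position = as.integer(slow_position)),
            class = "bscan")
}

#' Reference set: the slow-axis anchor B-scans
#'
#' @param ref_bscans list of `n_refs` slow-axis [bscan()] frames.
#' @param ref_fits list of their `poly_surface` fits as functions of the
#'   slow-axis coordinate y (may be NULL until preprocessing runs).
#' @param ref_x 0-based fast-axis column index of each reference plane.
#' @export
reference_set <- function(ref_bscans, ref_fits = NULL, ref_x) {
  if (!is.null(ref_fits) && length(ref_fits) != length(ref_bscans))
    abort_oct("ref_fits length must match ref_bscans", "octmoco_shape")
  if (length(ref_x) != length(ref_bscans))
    abort_oct("ref_x length must match ref_bscans", "octmoco_shape")
  structure(list(ref_bscans = ref_bscans, ref_fits = ref_fits,
                 ref_x = as.numeric(ref_x)),
            class = "reference_set")
}

#' C-scan volume
#'
#' @param protocol `scan_protocol`.
#' @param bscans ordered list of `n_slow` fast-axis frames.
#' @param references optional [reference_set()].
#' @export
cscan_volume <- function(protocol, bscans, references = NULL) {
  if (length(bscans) != protocol$n_slow)
    abort_oct(sprintf("expected %d fast B-scans, got %d",
                      protocol$n_slow, length(bscans)), "octmoco_shape")
  dims <- vapply(bscans, function(b) dim(b$pixels), integer(2))
  if (any(dims[1, ] != protocol$n_depth) || length(unique(dims[2, ])) != 1L)
    abort_oct("all frames must share dimensions matching the protocol",
              "octmoco_shape")
  structure(list(protocol = protocol, bscans = bscans,
                 references = references),
            class = "cscan_volume")
}

#' Detected surface trace of one B-scan
#'
#' @param depths per-column surface depth, fractional pixels (0-based z).
#' @param valid per-column logical; FALSE marks interpolated columns.
#' @export
surface_trace <- function(depths, valid = rep(TRUE, length(depths))) {
  if (length(valid) != length(depths))
    abort_oct("valid mask length must match depths", "octmoco_shape")
  structure(list(depths = as.numeric(depths), valid = as.logical(valid)),
            class = "surface_trace")
}

#' Diffraction-limited lateral resolution, 0.61 lambda / NA
#'
#' @param lambda_um center wavelength in micrometers.
#' @param na numerical aperture of the objective.
#' @return lateral resolution in micrometers.
#' @export
lateral_resolution_um <- function(lambda_um = 1.060, na = 0.05) {
  0.61 * lambda_um / na
}

#' Axial pixel pitch from imaging depth range
#'
#' @param depth_range_mm imaging depth range in millimeters.
#' @param n_depth axial pixels.
#' @return micrometers per axial pixel.
#' @export
axial_pitch_from_range <- function(depth_range_mm = 3.7, n_depth = 1024L) {
  depth_range_mm * 1000 / n_depth
}
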