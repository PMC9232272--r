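## Volume, trace and report I/O.
##
## A volume on disk is one multi-page TIFF (reference pages first, when
## present) plus a JSON sidecar `<file>.json` holding the scan protocol
## and the number of leading reference pages.

#' Write a C-scan volume to a multi-page TIFF with a JSON sidecar
#'
#' Reference frames (if attached) are stored as the first `n_refs`
#' pages, followed by the `n_slow` fast-axis frames, all depth-major.
#'
#' @param volume `cscan_volume`.
#' @param path output TIFF path; the sidecar goes to `paste0(path, ".json")`.
#' @param dtype pixel storage type, see [write_tiff_stack()].
#' @export
write_volume <- function(volume, path, dtype = "float32") {
  refs <- volume$references
  pages <- c(if (!is.null(refs)) lapply(refs$ref_bscans, `[[`, "pixels"),
             lapply(volume$bscans, `[[`, "pixels"))
  write_tiff_stack(pages, path, dtype)
  sidecar <- c(unclass(volume$protocol),
               list(ref_pages = if (is.null(refs)) 0L else length(refs$ref_bscans)))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a C-scan volume from a multi-page TIFF
#'
#' @param path TIFF file written by [write_volume()] (or any
#'   uncompressed grayscale stack with a matching sidecar/protocol).
#' @param protocol optional `scan_protocol`; when NULL it is read from
#'   the JSON sidecar.
#' @param ref_pages number of leading reference pages; when NULL it is
#'   taken from the sidecar (0 if there is none).
#' @return `cscan_volume` (with a `reference_set` when `ref_pages > 0`).
#' @export
read_volume <- function(path, protocol = NULL, ref_pages = NULL) {
  sidecar_path <- paste0(path, ".json")
  sidecar <- if (file.exists(sidecar_path)) jsonlite::fromJSON(sidecar_path)
  if (is.null(protocol)) {
    if (is.null(sidecar))
      abort_oct("no protocol given and no sidecar found", "octmoco_config")
    protocol <- do.call(scan_protocol, sidecar[intersect(names(sidecar), protocol_keys)])
  }
  if (is.null(ref_pages))
    ref_pages <- if (!is.null(sidecar$ref_pages)) as.integer(sidecar$ref_pages) else 0L
  stack <- read_tiff_stack(path)
  pages <- stack$pages
  if (length(pages) != protocol$n_slow + ref_pages)
    abort_oct(sprintf("expected %d pages (%d refs + %d frames), found %d",
                      protocol$n_slow + ref_pages, ref_pages, protocol$n_slow,
                      length(pages)), "octmoco_format")
  for (i in seq_len(ref_pages)) {
    d <- dim(pages[[i]])
    if (d[1] != protocol$n_depth || d[2] != protocol$n_slow)
      abort_oct(sprintf("reference page %d is %dx%d, expected %dx%d",
                        i, d[1], d[2], protocol$n_depth, protocol$n_slow),
                "octmoco_format")
  }
  for (i in seq_len(protocol$n_slow)) {
    d <- dim(pages[[ref_pages + i]])
    if (d[1] != protocol$n_depth || d[2] != protocol$n_fast)
      abort_oct(sprintf("page %d is %dx%d, expected %dx%d",
                        ref_pages + i, d[1], d[2], protocol$n_depth,
                        protocol$n_fast), "octmoco_format")
  }
  refs <- NULL
  if (ref_pages > 0L) {
    if (ref_pages != protocol$n_refs)
      abort_oct("reference page count does not match protocol n_refs",
                "octmoco_format")
    refs <- reference_set(
      ref_bscans = lapply(seq_len(ref_pages), function(i)
        bscan(pages[[i]], "slow", index = i - 1L,
              slow_position = protocol$ref_positions[i])),
      ref_x = protocol$ref_positions)
  }
  frames <- lapply(seq_len(protocol$n_slow), function(j)
    bscan(pages[[ref_pages + j]], "fast", index = ref_pages + j - 1L,
          slow_position = j - 1L))
  cscan_volume(protocol, frames, refs)
}

#' Write detected surface traces as CSV
#'
#' One row per (bscan_index, column); depths are written both in pixels
#' and in micrometers (`depth_px * axial_pitch_um`).
#'
#' @param traces list of `surface_trace`, one per frame (frame i gets
#'   `bscan_index = i - 1`).
#' @param path output CSV path.
#' @param axial_pitch_um axial pixel pitch for the `depth_um` column.
#' @export
write_surface_csv <- function(traces, path, axial_pitch_um = 3.6) {
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    if (any(!is.finite(tr$depths)))
      abort_oct("traces must be finite", "octmoco_value")
    data.frame(bscan_index = i - 1L,
               column = seq_along(tr$depths) - 1L,
               depth_px = tr$depths,
               depth_um = tr$depths * axial_pitch_um,
               valid = tr$valid)
  })
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(bscan_index = integer(), column = integer(),
                        depth_px = numeric(), depth_um = numeric(),
                        valid = logical())
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read surface traces back from CSV
#'
#' @param path CSV written by [write_surface_csv()].
#' @return list of `surface_trace`, ordered by `bscan_index`.
#' @export
read_surface_csv <- function(path) {
  df <- utils::read.csv(path)
  if (nrow(df) == 0L) return(list())
  lapply(sort(unique(df$bscan_index)), function(i) {
    d <- df[df$bscan_index == i, ]
    d <- d[order(d$column), ]
    surface_trace(d$depth_px, d$valid)
  })
}

#' Write / read a JSON evaluation report
#'
#' Reports round-trip losslessly (full double precision, no rounding).
#' @param report named list.
#' @param path JSON path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  if (!file.exists(path)) abort_oct(paste("no such file:", path), "octmoco_io")
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Write per-frame motion estimates as CSV
#'
#' Columns: frame index, estimated lateral shift and its cost, the
#' quadratic axial-model coefficients a0..a2 (in pixels) and the sampled
#' offsets at each reference plane.
#' @param motion data.frame as produced by [compensate_volume()].
#' @param path output CSV path.
#' @export
write_motion_csv <- function(motion, path) {
  utils::write.csv(motion, path, row.names = FALSE)
  invisible(path)
}
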