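## End-to-end motion compensation of a C-scan volume.

#' Compensation configuration
#'
#' @param preprocess `preprocess_config`.
#' @param search_px lateral search half-range (pixels).
#' @param crop_px lateral border crop per side applied after
#'   compensation; defaults to the preprocess `border_crop`.
#' @param lateral enable lateral compensation.
#' @param axial enable axial compensation.
#' @export
compensate_config <- function(preprocess = preprocess_config(),
                              search_px = 50L, crop_px = NULL,
                              lateral = TRUE, axial = TRUE) {
  structure(list(preprocess = preprocess,
                 search_px = as.integer(search_px),
                 crop_px = as.integer(crop_px %||% preprocess$border_crop),
                 lateral = isTRUE(lateral), axial = isTRUE(axial)),
            class = "compensate_config")
}

#' Fit the reference-plane surfaces of a volume
#'
#' Preprocesses each slow-axis reference B-scan, producing its surface
#' fit as a polynomial in the slow coordinate y.
#'
#' @param volume `cscan_volume` with a `reference_set`.
#' @param cfg `compensate_config`.
#' @return the volume's `reference_set` with `ref_fits` filled in.
#' @export
fit_references <- function(volume, cfg = compensate_config()) {
  refs <- volume$references
  if (is.null(refs)) abort_oct("volume has no reference set", "octmoco_value")
  refs$ref_fits <- lapply(refs$ref_bscans, function(b)
    preprocess_bscan(b, cfg$preprocess)$fit)
  refs
}

#' Motion-compensate a C-scan volume
#'
#' Per fast-axis B-scan, in order: preprocessing (segmentation + fit),
#' lateral shift estimation against frame 1 and image re-alignment,
#' axial offsets against the three reference planes, quadratic axial
#' model fit, and axial image/surface shift.  Borders are cropped last.
#' Frames whose processing fails are passed through uncompensated and
#' counted in the report.
#'
#' @param volume `cscan_volume` with references.
#' @param cfg `compensate_config`.
#' @return list: `volume` (compensated, cropped), `motion` (data.frame
#'   with per-frame lateral shift, cost, axial coefficients and
#'   reference offsets), `surfaces` (matrix, frames x cropped columns,
#'   compensated surface depth in pixels evaluated at integer columns
#'   in frame-1-aligned coordinates), `observed` (logical matrix of
#'   the same shape: TRUE where the frame actually acquired an A-scan
#'   at that aligned column, FALSE where the surface value is lateral
#'   extrapolation over columns vacated by the shift), `report`
#'   (failure log + config).
#' @export
compensate_volume <- function(volume, cfg = compensate_config()) {
  p <- volume$protocol
  refs <- fit_references(volume, cfg)
  n <- p$n_slow
  nref <- length(refs$ref_x)
  crop <- cfg$crop_px
  cols_kept <- (crop + 1L):(p$n_fast - crop)
  xs_eval <- cols_kept - 1           # 0-based aligned columns
  surfaces <- matrix(NA_real_, n, length(cols_kept))
  observed <- matrix(FALSE, n, length(cols_kept))
  shift_col <- rep(NA_integer_, n)
  cost_col <- rep(NA_real_, n)
  acoef <- matrix(NA_real_, n, max(3L, nref))
  aoffs <- matrix(NA_real_, n, nref)
  failed <- integer(0)
  msgs <- character(0)
  out_frames <- volume$bscans
  z1 <- NULL
  for (j in seq_len(n)) {
    ok <- tryCatch({
      frame <- volume$bscans[[j]]
      pp <- preprocess_bscan(frame, cfg$preprocess)
      z_t <- pp$fit
      if (cfg$lateral) {
        if (is.null(z1)) {
          z1 <- z_t
          ls <- structure(list(bscan_index = j - 1L, shift_px = 0L, cost = 0),
                          class = "lateral_shift")
        } else {
          ls <- estimate_lateral_shift(z_t, z1, cfg$search_px)
        }
        if (ls$shift_px != 0L) {
          frame <- apply_lateral_shift(frame, ls)
          z_t <- poly_shift(z_t, ls$shift_px)
        }
        shift_col[j] <- ls$shift_px
        cost_col[j] <- ls$cost
      } else {
        shift_col[j] <- 0L
        cost_col[j] <- 0
      }
      if (cfg$axial) {
        a <- axial_offsets(z_t, refs, y_t = frame$slow_position)
        model <- fit_axial_motion(refs$ref_x, a)
        ca <- compensate_axial(frame, z_t, model)
        frame <- ca$bscan
        z_t <- ca$surface
        acoef[j, seq_along(model$coeffs)] <- model$coeffs
        aoffs[j, ] <- a
      }
      out_frames[[j]] <- frame
      surfaces[j, ] <- poly_eval(z_t, xs_eval)
      # columns vacated by the lateral shift hold no acquired A-scan;
      # the surface there is polynomial extrapolation, not measurement
      dl <- shift_col[j]
      observed[j, ] <- xs_eval >= -dl & xs_eval <= (p$n_fast - 1) - dl
      TRUE
    }, octmoco_error = function(e) {
      msgs <<- c(msgs, sprintf("frame %d: %s", j - 1L, conditionMessage(e)))
      FALSE
    })
    if (!ok) failed <- c(failed, j - 1L)
  }
  comp <- cscan_volume(p, out_frames, refs)
  comp <- crop_borders(comp, crop)
  motion <- data.frame(frame = seq_len(n) - 1L,
                       lateral_px = shift_col, lateral_cost = cost_col)
  for (k in seq_len(ncol(acoef)))
    motion[[paste0("a", k - 1L)]] <- acoef[, k]
  for (k in seq_len(nref))
    motion[[paste0("ref_offset", k)]] <- aoffs[, k]
  list(volume = comp,
       motion = motion,
       surfaces = surfaces,
       observed = observed,
       report = list(n_frames = n, n_failed = length(failed),
                     failed_frames = failed, messages = msgs,
                     crop_px = crop, search_px = cfg$search_px))
}

#' Segment every frame of a volume without compensating
#'
#' Used to build the reference surface matrix of a static (motion-free)
#' scan for evaluation against a compensated result.
#'
#' @param volume `cscan_volume`.
#' @param cfg `compensate_config`.
#' @param crop_px columns dropped per side before evaluation (defaults
#'   to the config crop so shapes match [compensate_volume()] output).
#' @return matrix frames x cropped columns of fitted surface depths (px).
#' @export
volume_surfaces <- function(volume, cfg = compensate_config(),
                            crop_px = NULL) {
  p <- volume$protocol
  crop <- crop_px %||% cfg$crop_px
  cols <- ((crop + 1L):(p$n_fast - crop)) - 1L
  t(vapply(volume$bscans, function(b)
    poly_eval(preprocess_bscan(b, cfg$preprocess)$fit, cols),
    numeric(length(cols))))
}
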