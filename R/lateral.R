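## Lateral (x) motion estimation and removal.
##
## Every fast-axis surface fit z_t is aligned to the first frame's fit
## z_1 by the integer shift minimizing the variance of the absolute
## surface difference over the overlapping columns.  Sign convention:
## positive shift means the sample moved toward +x between frame 1 and
## frame t, i.e. z_t(x + shift) re-aligns with z_1(x).

#' Estimate the lateral shift between two surface fits
#'
#' Exhaustive integer search of
#' `argmin_dl var(|z_t(x + dl) - z_1(x)|)` over `dl` in
#' `[-search_px, search_px]`, evaluated at all integer x where both
#' polynomials are inside their fitted domains.  Shifts whose overlap
#' is below 10 columns are skipped.  Ties go to the smallest `|dl|`,
#' then to the negative one.
#'
#' @param z_t `poly_surface` of frame t.
#' @param z_1 `poly_surface` of the target (first) frame.
#' @param search_px search half-range in pixels (default 50).
#' @return object of class `lateral_shift` with fields `bscan_index`
#'   (NA until assigned), `shift_px` and `cost`.
#' @export
estimate_lateral_shift <- function(z_t, z_1, search_px = 50L) {
  if (!is_count(search_px, 0L))
    abort_oct("search_px must be a non-negative integer", "octmoco_value")
  dls <- -search_px:search_px
  costs <- rep(NA_real_, length(dls))
  for (k in seq_along(dls)) {
    dl <- dls[k]
    lo <- max(ceiling(z_1$domain[1]), ceiling(z_t$domain[1] - dl))
    hi <- min(floor(z_1$domain[2]), floor(z_t$domain[2] - dl))
    if (hi - lo + 1 < 10) next
    x <- lo:hi
    d <- abs(poly_eval(z_t, x + dl) - poly_eval(z_1, x))
    costs[k] <- stats::var(d)
  }
  if (all(is.na(costs)))
    abort_oct("no admissible shift: overlap below 10 columns everywhere",
              "octmoco_no_overlap")
  ok <- which(!is.na(costs))
  ord <- ok[order(costs[ok], abs(dls[ok]), dls[ok])]
  best <- ord[1]
  structure(list(bscan_index = NA_integer_,
                 shift_px = as.integer(dls[best]),
                 cost = costs[best]),
            class = "lateral_shift")
}

#' Apply a lateral shift to a B-scan
#'
#' Columns are translated by `-shift_px` (output column x takes input
#' column `x + shift_px`); vacated columns are zero-filled and recorded
#' in the `"filled_cols"` attribute (0-based).
#'
#' @param frame [bscan()].
#' @param shift `lateral_shift` or integer pixels.
#' @export
apply_lateral_shift <- function(frame, shift) {
  dl <- if (inherits(shift, "lateral_shift")) shift$shift_px else as.integer(shift)
  px <- frame$pixels
  nc <- ncol(px)
  if (abs(dl) >= nc) abort_oct("shift exceeds image width", "octmoco_value")
  out <- matrix(0, nrow(px), nc)
  src <- seq_len(nc) + dl
  ok <- src >= 1L & src <= nc
  out[, ok] <- px[, src[ok]]
  res <- frame
  res$pixels <- out
  attr(res, "filled_cols") <- which(!ok) - 1L
  res
}

#' Crop lateral borders of a volume
#'
#' Removes `crop` columns from both sides of every fast-axis frame (to
#' discard the empty A-scans produced by lateral compensation) and
#' updates the protocol's `n_fast` and `ref_positions` consistently.
#'
#' @param volume `cscan_volume`.
#' @param crop columns to remove per side.
#' @export
crop_borders <- function(volume, crop) {
  if (!is_count(crop, 0L)) abort_oct("crop must be a non-negative integer",
                                     "octmoco_value")
  if (crop == 0L) return(volume)
  p <- volume$protocol
  if (2L * crop >= p$n_fast)
    abort_oct("crop removes the whole image", "octmoco_value")
  keep <- (crop + 1L):(p$n_fast - crop)
  new_refpos <- p$ref_positions - crop
  if (any(new_refpos < 0L) || any(new_refpos > length(keep) - 1L))
    new_refpos <- pmin(pmax(new_refpos, 0L), length(keep) - 1L)
  p2 <- p
  p2$n_fast <- length(keep)
  p2$ref_positions <- as.integer(new_refpos)
  frames <- lapply(volume$bscans, function(b) {
    b$pixels <- b$pixels[, keep, drop = FALSE]
    b
  })
  refs <- volume$references
  if (!is.null(refs)) refs$ref_x <- as.numeric(new_refpos)
  structure(list(protocol = p2, bscans = frames, references = refs),
            class = "cscan_volume")
}
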