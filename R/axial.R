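## Axial (z) motion estimation from the slow-axis reference planes.
##
## For frame t at slow position y_t, the surface fit is compared with
## each reference fit at the reference's fast-axis column x_i^r:
## a(x_i) = z_t(x_i^r) - z_i^r.  The per-column axial motion a(x) is the
## unique polynomial of order n_refs - 1 through these offsets (a
## quadratic for the default three references) and is subtracted from
## both the image (rounded to whole pixels) and the surface fit (kept
## fractional): f(x) = z(x) - a(x).

#' Reference surface depths at a slow-axis position
#'
#' Evaluates every reference plane's fitted surface (a polynomial in
#' the slow coordinate y) at `y_t`.
#'
#' @param refset `reference_set` with fitted `ref_fits`.
#' @param y_t slow-axis index of the frame (0-based).
#' @return numeric vector `z_i^r`, one per reference.
#' @export
reference_depths_at <- function(refset, y_t) {
  if (is.null(refset$ref_fits))
    abort_oct("reference surfaces not fitted yet", "octmoco_value")
  vapply(refset$ref_fits, function(ps) {
    if (y_t < ps$domain[1] || y_t > ps$domain[2])
      abort_oct(sprintf("slow position %g outside reference fit domain [%g, %g]",
                        y_t, ps$domain[1], ps$domain[2]), "octmoco_domain")
    poly_eval(ps, y_t)
  }, numeric(1))
}

#' Axial offsets of a frame at the reference planes
#'
#' `a(x_i) = z_t(x_i^r) - z_i^r`, positive when the surface appears
#' deeper than the reference.  `z_t` is evaluated at the reference
#' columns even when they fall slightly outside its fitted domain
#' (polynomial extrapolation), which happens after large lateral
#' shifts; the published method behaves the same way.
#'
#' @param z_t `poly_surface` of the (laterally compensated) frame.
#' @param refset `reference_set`.
#' @param y_t slow-axis index of the frame.
#' @return numeric vector of offsets in pixels, one per reference.
#' @export
axial_offsets <- function(z_t, refset, y_t) {
  zr <- reference_depths_at(refset, y_t)
  poly_eval(z_t, refset$ref_x) - zr
}

#' Fit the per-column axial motion polynomial
#'
#' Unique interpolating polynomial (Lagrange-equivalent, solved on the
#' Vandermonde system) through the `(x_i^r, a_i)` points: a quadratic
#' for three references, a line for two.
#'
#' @param x reference fast-axis columns.
#' @param a axial offsets at those columns (pixels).
#' @return object of class `axial_motion` with ascending `coeffs`
#'   (`a0, a1, a2, ...`), the defining `ref_x` and `ref_offsets`.
#' @export
fit_axial_motion <- function(x, a) {
  x <- as.numeric(x)
  a <- as.numeric(a)
  if (length(x) != length(a) || length(x) < 2L)
    abort_oct("need at least two (x, offset) points", "octmoco_value")
  if (anyDuplicated(x)) abort_oct("reference x positions must be distinct",
                                  "octmoco_value")
  n <- length(x)
  xs <- scale(x, center = mean(x), scale = max(abs(x - mean(x))))
  V <- outer(as.numeric(xs), 0:(n - 1L), `^`)
  cf_s <- solve(V, a)
  # map back to raw x: u = (x - c) / s
  cshift <- attr(xs, "scaled:center")
  sdiv <- attr(xs, "scaled:scale")
  lin <- c(-cshift / sdiv, 1 / sdiv)
  out <- numeric(1)
  basis <- 1
  for (k in seq_len(n)) {
    out <- poly_add(out, cf_s[k] * basis)
    basis <- poly_mul(basis, lin)
  }
  structure(list(bscan_index = NA_integer_,
                 coeffs = out[seq_len(n)],
                 ref_x = x, ref_offsets = a),
            class = "axial_motion")
}

#' Evaluate an axial motion model
#'
#' @param model `axial_motion`.
#' @param x columns (0-based), vectorized.
#' @export
eval_axial <- function(model, x) {
  cf <- model$coeffs
  out <- rep(cf[length(cf)], length(x))
  if (length(cf) > 1L)
    for (k in seq(length(cf) - 1L, 1L)) out <- out * x + cf[k]
  out
}

#' Subtract axial motion from a B-scan
#'
#' Every A-line (column x) is translated axially by `-round(a(x))` with
#' zero fill; the reported compensated surface `f(x) = z(x) - a(x)`
#' keeps full (unrounded) precision, which is how sub-pixel residual
#' errors remain measurable despite whole-voxel image shifts.
#'
#' @param frame [bscan()].
#' @param z_t `poly_surface` of the frame (laterally compensated).
#' @param model `axial_motion`.
#' @return list with `bscan` (shifted image) and `surface`
#'   (`poly_surface` f).
#' @export
compensate_axial <- function(frame, z_t, model) {
  px <- frame$pixels
  nr <- nrow(px)
  nc <- ncol(px)
  a <- eval_axial(model, seq_len(nc) - 1)
  if (any(!is.finite(a)) || any(abs(a) >= nr))
    abort_oct("axial motion exceeds imaging depth", "octmoco_value")
  sh <- as.integer(round(a))
  out <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    src <- seq_len(nr) + sh[j]
    ok <- src >= 1L & src <= nr
    out[ok, j] <- px[src[ok], j]
  }
  res <- frame
  res$pixels <- out
  f <- poly_surface(poly_add(z_t$coeffs, -model$coeffs)[
         seq_len(max(length(z_t$coeffs), length(model$coeffs)))],
       z_t$domain)
  list(bscan = res, surface = f)
}
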