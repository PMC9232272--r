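## Per-B-scan segmentation of the anterior corneal surface.
##
## Pipeline: Gaussian smoothing -> saturation-stripe removal by axial
## mean-line subtraction -> adaptive (local-mean) thresholding ->
## largest connected component -> initial per-column surface ->
## gradient refinement on the raw image -> polynomial fit.

#' Preprocessing configuration
#'
#' @param gauss_size side of the square Gaussian kernel (10).
#' @param gauss_sigma Gaussian standard deviation in pixels (4).
#' @param mean_filter_len taps of the axial averaging filter A (40,
#'   weight 1/40 each), applied along depth so that depth-constant
#'   saturation stripes cancel in the subtraction.
#' @param refine_window half-width in pixels of the gradient search
#'   around the initial boundary (15).
#' @param fit_order polynomial order for the surface fit (4).
#' @param threshold_window side of the adaptive-threshold neighborhood (64).
#' @param threshold_offset relative offset: a pixel is foreground iff its
#'   value exceeds `local_mean * (1 + threshold_offset)` (0).
#' @param border_crop lateral pixels cropped per side after compensation (50).
#' @param gradient_sqrt if TRUE the gradient image is
#'   `sqrt((S*I)^2 + (P*I)^2)` instead of the squared form; the squared
#'   form is the default (see [gradient_image()]).
#' @export
preprocess_config <- function(gauss_size = 10L, gauss_sigma = 4,
                              mean_filter_len = 40L, refine_window = 15L,
                              fit_order = 4L, threshold_window = 64L,
                              threshold_offset = 0,
                              border_crop = 50L, gradient_sqrt = FALSE) {
  for (nm in c("gauss_size", "mean_filter_len", "refine_window",
               "threshold_window"))
    if (!is_count(get(nm))) abort_oct(paste(nm, "must be a positive integer"),
                                      "octmoco_config")
  if (!is_count(fit_order) || fit_order < 2L || fit_order > 6L)
    abort_oct("fit_order must be in [2, 6]", "octmoco_config")
  if (!is_number(gauss_sigma) || gauss_sigma <= 0)
    abort_oct("gauss_sigma must be > 0", "octmoco_config")
  structure(list(gauss_size = as.integer(gauss_size), gauss_sigma = gauss_sigma,
                 mean_filter_len = as.integer(mean_filter_len),
                 refine_window = as.integer(refine_window),
                 fit_order = as.integer(fit_order),
                 threshold_window = as.integer(threshold_window),
                 threshold_offset = threshold_offset,
                 border_crop = as.integer(border_crop),
                 gradient_sqrt = isTRUE(gradient_sqrt)),
            class = "preprocess_config")
}

#' @keywords internal
gaussian_kernel <- function(size, sigma) {
  o <- seq_len(size) - (size + 1) / 2       # symmetric offsets, e.g. -4.5..4.5
  g <- exp(-o^2 / (2 * sigma^2))
  K <- outer(g, g)
  K / sum(K)
}

#' Gaussian speckle smoothing
#'
#' Same-size correlation of the B-scan with the normalized `size x size`
#' sampled Gaussian, replicate padding.
#'
#' @param pixels numeric matrix (rows = depth).
#' @param cfg `preprocess_config`.
#' @return smoothed matrix, same shape.
#' @export
gaussian_smooth <- function(pixels, cfg = preprocess_config()) {
  if (!is.matrix(pixels)) abort_oct("input must be a 2D matrix", "octmoco_shape")
  # separable: the normalized kernel is outer(g, g) with g normalized,
  # so two 1D passes equal the full 2D correlation (replicate padding
  # commutes with per-column/per-row filtering)
  g <- exp(-(seq_len(cfg$gauss_size) - (cfg$gauss_size + 1) / 2)^2 /
             (2 * cfg$gauss_sigma^2))
  g <- g / sum(g)
  tmp <- filter2_replicate(pixels, matrix(g, ncol = 1))
  filter2_replicate(tmp, matrix(g, nrow = 1))
}

#' Saturation-stripe removal by axial mean-line subtraction
#'
#' `I = Ig - Ig * A` where A is the axial averaging filter
#' (`mean_filter_len` taps along depth, each `1/len`), replicate padded.
#' A saturated A-line — a bright stripe constant along depth — equals
#' its own axial running mean and cancels.  Output values may be
#' negative; they are kept as-is for thresholding.
#'
#' @inheritParams gaussian_smooth
#' @export
remove_saturation <- function(pixels, cfg = preprocess_config()) {
  if (!is.matrix(pixels)) abort_oct("input must be a 2D matrix", "octmoco_shape")
  if (nrow(pixels) < cfg$mean_filter_len)
    abort_oct(sprintf("image must have at least %d depth pixels",
                      cfg$mean_filter_len), "octmoco_shape")
  pixels - runmean_depth(pixels, cfg$mean_filter_len)
}

#' Adaptive (local-mean) thresholding
#'
#' A pixel is foreground iff its value strictly exceeds the mean of its
#' `threshold_window`-square replicate-padded neighborhood scaled by
#' `(1 + threshold_offset)`.  The image is rectified (`max(I, 0)`)
#' first: OCT intensities are non-negative, and the small negative
#' halo the mean-line subtraction leaves around bright bands would
#' otherwise pull the local mean below zero and promote the empty
#' background beside the surface into foreground, breaking the
#' guarantee that the surface band is the largest bright component.
#'
#' @inheritParams gaussian_smooth
#' @return logical matrix.
#' @export
adaptive_threshold <- function(pixels, cfg = preprocess_config()) {
  if (!is.matrix(pixels)) abort_oct("input must be a 2D matrix", "octmoco_shape")
  r <- pmax(pixels, 0)
  mu <- local_mean_replicate(r, cfg$threshold_window)
  r > mu * (1 + cfg$threshold_offset)
}

#' Keep the largest 8-connected foreground component
#'
#' Ties on pixel count are broken by the component containing the
#' brightest source pixel (when `intensity` is given), then by the
#' smallest (row, column) coordinate among component pixels.
#'
#' @param mask logical matrix.
#' @param intensity optional numeric matrix of source intensities used
#'   for tie-breaking.
#' @return logical matrix with only the selected component set.
#' @export
largest_component <- function(mask, intensity = NULL) {
  if (!is.matrix(mask) || !is.logical(mask))
    abort_oct("mask must be a logical matrix", "octmoco_shape")
  if (!any(mask)) abort_oct("no surface found (empty mask)", "octmoco_no_surface")
  lab <- label_components8(mask)
  sizes <- tabulate(lab[mask])
  best <- which(sizes == max(sizes))
  if (length(best) > 1L && !is.null(intensity)) {
    peak <- vapply(best, function(b) max(intensity[lab == b]), numeric(1))
    best <- best[peak == max(peak)]
  }
  if (length(best) > 1L) {
    # smallest (row, col) among each candidate's pixels, lexicographic
    key <- vapply(best, function(b) {
      w <- which(lab == b, arr.ind = TRUE)
      min(w[, 1] * (ncol(mask) + 1) + w[, 2])
    }, numeric(1))
    best <- best[which.min(key)]
  }
  lab == best[1]
}

#' 8-connected component labelling (via igraph)
#' @keywords internal
label_components8 <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  idx <- matrix(0L, nr, nc)
  fg <- which(mask)
  idx[fg] <- seq_along(fg)
  edges <- list()
  shift_pairs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  for (s in shift_pairs) {
    dr <- s[1]; dc <- s[2]
    a_rows <- seq_len(nr - dr)
    a_cols <- if (dc >= 0L) seq_len(nc - dc) else seq(1L - dc, nc)
    A <- idx[a_rows, a_cols, drop = FALSE]
    B <- idx[a_rows + dr, a_cols + dc, drop = FALSE]
    keep <- A > 0L & B > 0L
    if (any(keep)) edges[[length(edges) + 1L]] <- rbind(A[keep], B[keep])
  }
  memb <- if (length(edges)) {
    e <- do.call(cbind, edges)
    gr <- igraph::graph_from_edgelist(t(e), directed = FALSE)
    gr <- igraph::add_vertices(gr, max(0L, length(fg) - igraph::vcount(gr)))
    igraph::components(gr)$membership
  } else {
    seq_along(fg)
  }
  lab <- matrix(0L, nr, nc)
  lab[fg] <- memb[seq_along(fg)]
  lab
}

#' Initial surface: shallowest pixel of the component per column
#'
#' Columns without foreground are marked invalid and filled by linear
#' interpolation from valid neighbors (edge columns take the nearest
#' valid value).
#'
#' @param component logical matrix, the selected component.
#' @return `surface_trace` with 0-based depths.
#' @export
initial_surface <- function(component) {
  if (!any(component)) abort_oct("no surface found (empty component)",
                                 "octmoco_no_surface")
  nc <- ncol(component)
  depths <- rep(NA_real_, nc)
  for (j in seq_len(nc)) {
    r <- which(component[, j])
    if (length(r)) depths[j] <- r[1] - 1     # 0-based depth
  }
  valid <- !is.na(depths)
  if (!any(valid)) abort_oct("no valid surface column", "octmoco_no_surface")
  if (!all(valid)) {
    filled <- stats::approx(x = which(valid), y = depths[valid],
                            xout = seq_len(nc), method = "linear", rule = 2)$y
    depths[!valid] <- filled[!valid]
  }
  surface_trace(depths, valid)
}

#' High-pass gradient image for boundary refinement
#'
#' `F = (S * I0)^2 + (P * I0)^2` combining a Sobel and a Prewitt kernel
#' oriented along depth (rows), squared and summed without a square
#' root, as used for boundary refinement.  Setting `gradient_sqrt` in
#' the configuration yields the magnitude `sqrt(F)` instead (the
#' ranking within an A-line, which is all the refinement uses, is
#' unchanged).
#'
#' @param pixels raw (unsmoothed) B-scan matrix.
#' @param cfg `preprocess_config`.
#' @return non-negative matrix, same shape.
#' @export
gradient_image <- function(pixels, cfg = preprocess_config()) {
  if (!is.matrix(pixels)) abort_oct("input must be a 2D matrix", "octmoco_shape")
  # both kernels factor as outer(c(1, 0, -1), smoothing row); apply the
  # two 1D passes (equal to the full 3x3 correlation under replicate padding)
  d <- filter2_replicate(pixels, matrix(c(1, 0, -1), ncol = 1))
  Sg <- filter2_replicate(d, matrix(c(1, 2, 1), nrow = 1))
  Pg <- filter2_replicate(d, matrix(c(1, 1, 1), nrow = 1))
  Fv <- Sg^2 + Pg^2
  if (cfg$gradient_sqrt) sqrt(Fv) else Fv
}

#' Refine a surface trace against the gradient image
#'
#' Per column, the depth moves to the row of maximal gradient within
#' `refine_window` pixels of the initial depth (window clipped to the
#' image).  Ties go to the row closest to the initial depth, then to
#' the shallower row.
#'
#' @param trace initial `surface_trace`.
#' @param grad gradient matrix from [gradient_image()].
#' @param cfg `preprocess_config`.
#' @export
refine_surface <- function(trace, grad, cfg = preprocess_config()) {
  nc <- ncol(grad)
  if (length(trace$depths) != nc)
    abort_oct("trace and gradient column counts differ", "octmoco_shape")
  w <- cfg$refine_window
  nr <- nrow(grad)
  depths <- trace$depths
  out <- depths
  for (j in seq_len(nc)) {
    z0 <- round(depths[j])                       # 0-based
    lo <- max(0, z0 - w)
    hi <- min(nr - 1, z0 + w)
    v <- grad[(lo:hi) + 1, j]
    m <- max(v)
    cand <- (lo:hi)[v == m]
    d <- abs(cand - depths[j])
    cand <- cand[d == min(d)]
    out[j] <- min(cand)
  }
  surface_trace(out, trace$valid)
}

#' Full preprocessing of one B-scan
#'
#' Runs the six stages in order and returns both the refined trace and
#' its polynomial fit.  Stage failures are re-signalled with the stage
#' name prefixed.
#'
#' @param frame a [bscan()] or a plain pixel matrix.
#' @param cfg `preprocess_config`.
#' @return list with `trace` (`surface_trace`) and `fit` (`poly_surface`).
#' @export
preprocess_bscan <- function(frame, cfg = preprocess_config()) {
  pixels <- if (inherits(frame, "bscan")) frame$pixels else frame
  stage <- function(name, expr) {
    tryCatch(expr, octmoco_error = function(e) {
      abort_oct(sprintf("[%s] %s", name, conditionMessage(e)),
                class(e)[1])
    })
  }
  sm <- stage("gaussian_smooth", gaussian_smooth(pixels, cfg))
  sat <- stage("remove_saturation", remove_saturation(sm, cfg))
  mask <- stage("adaptive_threshold", adaptive_threshold(sat, cfg))
  if (!any(mask)) abort_oct("[adaptive_threshold] no surface found",
                            "octmoco_no_surface")
  comp <- stage("largest_component", largest_component(mask, intensity = sat))
  # sanity: a surface band is thin but laterally extended; reject
  # percolated noise (too large) and isolated blobs (too narrow)
  if (sum(comp) > 0.25 * length(comp) ||
      sum(colSums(comp) > 0) < 0.5 * ncol(comp))
    abort_oct("no surface found (foreground is not band-like)",
              "octmoco_no_surface")
  tr0 <- stage("initial_surface", initial_surface(comp))
  grad <- stage("gradient_image", gradient_image(pixels, cfg))
  tr <- stage("refine_surface", refine_surface(tr0, grad, cfg))
  fit <- stage("fit_surface", fit_surface(tr, cfg$fit_order))
  list(trace = tr, fit = fit)
}
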