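## Internal helpers shared across modules.

#' @keywords internal
abort_oct <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "octmoco_error"), call = call))
}

#' @keywords internal
is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x) && x >= min
}

#' @keywords internal
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded simulation helpers do not
#' disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate after seeding.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a per-frame RNG seed from a master seed
#'
#' Keeps results below 2^31 - 1 so they remain valid R integer seeds.
#' @keywords internal
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 65537 + as.numeric(k) * 97 + 11) %% 2147483629)
}

#' Replicate-pad a matrix
#'
#' Edge rows/columns are repeated outward; this is the boundary rule used
#' by every filtering operation in the package.
#' @keywords internal
pad_replicate <- function(img, top, bottom, left, right) {
  nr <- nrow(img)
  nc <- ncol(img)
  ri <- c(rep.int(1L, top), seq_len(nr), rep.int(nr, bottom))
  ci <- c(rep.int(1L, left), seq_len(nc), rep.int(nc, right))
  img[ri, ci, drop = FALSE]
}

#' 2D linear filtering (correlation) with replicate padding
#'
#' Computes `out(i, j) = sum_{a,b} K(a, b) * I(i + a - 1 - ca, j + b - 1 - cb)`
#' with the anchor at `(ca, cb) = (floor(nrow(K)/2), floor(ncol(K)/2))`
#' (0-based) and replicate padding, i.e. the usual image-processing
#' "same-size correlation".  For the symmetric kernels used in the
#' pipeline this coincides with convolution.
#'
#' @param img numeric matrix.
#' @param kernel numeric matrix, not larger than `img`.
#' @return matrix of the same size as `img`.
#' @export
filter2_replicate <- function(img, kernel) {
  if (!is.matrix(img) || !is.numeric(img))
    abort_oct("`img` must be a numeric matrix", "octmoco_shape")
  if (!is.matrix(kernel)) kernel <- as.matrix(kernel)
  kr <- nrow(kernel)
  kc <- ncol(kernel)
  ca <- kr %/% 2L
  cb <- kc %/% 2L
  P <- pad_replicate(img, ca, kr - 1L - ca, cb, kc - 1L - cb)
  nr <- nrow(img)
  nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (a in seq_len(kr)) {
    for (b in seq_len(kc)) {
      w <- kernel[a, b]
      if (w == 0) next
      out <- out + w * P[(a - 1L) + seq_len(nr), (b - 1L) + seq_len(nc), drop = FALSE]
    }
  }
  out
}

#' Running mean along depth (columns of A-lines), replicate padded
#'
#' Cumulative-sum implementation of the `len x 1` box filter with the
#' anchor at `floor(len/2)`; equals
#' `filter2_replicate(img, matrix(1/len, len, 1))` to rounding error.
#' @keywords internal
runmean_depth <- function(img, len) {
  lo <- len %/% 2L
  hi <- len - 1L - lo
  P <- pad_replicate(img, lo, hi, 0L, 0L)
  S <- rbind(0, apply(P, 2L, cumsum))
  i <- seq_len(nrow(img))
  (S[i + len, , drop = FALSE] - S[i, , drop = FALSE]) / len
}

#' Local mean over a square replicate-padded window
#'
#' Integral-image implementation; equals the w-by-w box filter with the
#' anchor at `floor(w/2)` (0-based).
#' @keywords internal
local_mean_replicate <- function(img, w) {
  nr <- nrow(img)
  nc <- ncol(img)
  if (w > nr || w > nc)
    abort_oct("window larger than image", "octmoco_shape")
  lo <- w %/% 2L
  hi <- w - 1L - lo
  P <- pad_replicate(img, lo, hi, lo, hi)
  # integral image with a zero first row/column
  S <- matrix(0, nrow(P) + 1L, ncol(P) + 1L)
  S[-1L, -1L] <- apply(P, 2L, cumsum)
  S[-1L, -1L] <- t(apply(S[-1L, -1L, drop = FALSE], 1L, cumsum))
  i <- seq_len(nr)
  j <- seq_len(nc)
  (S[i + w, j + w, drop = FALSE] - S[i, j + w, drop = FALSE] -
     S[i + w, j, drop = FALSE] + S[i, j, drop = FALSE]) / (w * w)
}
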