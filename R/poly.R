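## Polynomial surface representation and least-squares fitting.
##
## A fitted surface is stored with ascending coefficients:
## coeffs[k] multiplies x^(k-1), so z(x) = p[n+1] x^n + ... + p[1],
## with x in 0-based column-index units.

#' Construct a polynomial surface
#'
#' @param coeffs ascending coefficients (`coeffs[k]` multiplies `x^(k-1)`).
#' @param domain length-2 numeric, the fitted column range `[x_min, x_max]`.
#' @return an object of class `poly_surface`.
#' @export
poly_surface <- function(coeffs, domain) {
  coeffs <- as.numeric(coeffs)
  if (length(coeffs) < 1L || any(!is.finite(coeffs)))
    abort_oct("coefficients must be finite and non-empty", "octmoco_value")
  if (length(domain) != 2L || domain[1] > domain[2])
    abort_oct("domain must be an increasing length-2 range", "octmoco_value")
  structure(list(order = length(coeffs) - 1L,
                 coeffs = coeffs,
                 domain = as.numeric(domain)),
            class = "poly_surface")
}

#' Evaluate a polynomial surface
#'
#' Horner evaluation; values outside `domain` are extrapolated (callers
#' that must stay inside the fitted range check the domain themselves).
#'
#' @param ps `poly_surface`.
#' @param x numeric vector of column positions (0-based).
#' @export
poly_eval <- function(ps, x) {
  cf <- ps$coeffs
  out <- rep(cf[length(cf)], length(x))
  if (length(cf) > 1L)
    for (k in seq(length(cf) - 1L, 1L)) out <- out * x + cf[k]
  out
}

#' @keywords internal
poly_mul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' @keywords internal
poly_add <- function(a, b) {
  n <- max(length(a), length(b))
  out <- numeric(n)
  out[seq_along(a)] <- a
  out[seq_along(b)] <- out[seq_along(b)] + b
  out
}

#' Shift a polynomial's argument
#'
#' Returns the ascending coefficients of `p(x + h)` given those of `p(x)`.
#' @keywords internal
poly_compose_shift <- function(coeffs, h) {
  out <- numeric(1)
  basis <- 1
  for (k in seq_along(coeffs)) {
    out <- poly_add(out, coeffs[k] * basis)
    basis <- poly_mul(basis, c(h, 1))
  }
  out[seq_along(coeffs)]
}

#' Translate a fitted surface laterally
#'
#' `poly_shift(ps, h)` returns the surface `q` with `q(x) = ps(x + h)`;
#' the domain moves by `-h` accordingly.
#' @param ps `poly_surface`.
#' @param h shift in columns.
#' @export
poly_shift <- function(ps, h) {
  poly_surface(poly_compose_shift(ps$coeffs, h), ps$domain - h)
}

#' Fit a polynomial to a detected surface trace
#'
#' Least-squares fit of an order-`n` polynomial through the valid columns
#' of a surface trace, solved by the normal equations
#' `P = (V'V)^{-1} V'Z` on a Vandermonde matrix.  Columns are rescaled to
#' `[-1, 1]` internally for conditioning; the returned coefficients are
#' mapped back to raw 0-based column units.
#'
#' @param trace a `surface_trace` (or list with `depths` and `valid`).
#' @param order polynomial order `n` (default 4).
#' @return a `poly_surface` whose `domain` is the span of valid columns.
#' @export
fit_surface <- function(trace, order = 4L) {
  if (!is_count(order, min = 1L))
    abort_oct("`order` must be a positive integer", "octmoco_value")
  depths <- trace$depths
  valid <- if (is.null(trace$valid)) rep(TRUE, length(depths)) else trace$valid
  x <- which(valid) - 1   # 0-based column indices
  z <- depths[valid]
  if (length(x) < order + 1L || length(unique(x)) < order + 1L)
    abort_oct(sprintf("need at least %d distinct valid columns for an order-%d fit",
                      order + 1L, order), "octmoco_rank")
  xmin <- min(x)
  xmax <- max(x)
  s <- 2 / (xmax - xmin)
  u <- s * (x - xmin) - 1
  V <- outer(u, 0:order, `^`)
  G <- crossprod(V)
  cf_u <- tryCatch(solve(G, crossprod(V, z)),
                   error = function(e) abort_oct("rank-deficient polynomial system",
                                                 "octmoco_rank"))
  # map z(u) with u = s*(x - xmin) - 1 back to raw-x coefficients
  lin <- c(-s * xmin - 1, s)   # u as a polynomial in x
  out <- numeric(1)
  basis <- 1
  for (k in seq_len(order + 1L)) {
    out <- poly_add(out, cf_u[k] * basis)
    basis <- poly_mul(basis, lin)
  }
  poly_surface(out[seq_len(order + 1L)], c(xmin, xmax))
}

#' Root-mean-square residual of a surface fit
#'
#' @param ps `poly_surface`.
#' @param trace surface trace the fit should explain.
#' @param valid_only use only valid columns (default TRUE).
#' @export
fit_residual_rms <- function(ps, trace, valid_only = TRUE) {
  keep <- if (valid_only && !is.null(trace$valid)) trace$valid
          else rep(TRUE, length(trace$depths))
  x <- which(keep) - 1
  r <- poly_eval(ps, x) - trace$depths[keep]
  sqrt(mean(r^2))
}
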