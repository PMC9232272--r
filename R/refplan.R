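## Reference-placement accuracy theory.
##
## The compensation accuracy contributed by a reference plane at column
## mu is modelled as a peak-normalized Gaussian R(x; mu, sigma).  With
## three references at mu = (1/2 - alpha, 1/2, 1/2 + alpha) * m the
## combined accuracy Y(x) is an inverse-distance weighted mixture of
## the R_i, the total error is E(alpha, sigma) = sum_x [1 - Y(x)], and
## the spacing ratio alpha is chosen to minimize E.

#' Accuracy model for three reference planes
#'
#' @param m maximum A-scan index (default 1023, i.e. 1024 A-scans).
#' @param sigma width of the per-reference Gaussian accuracy (pixels).
#' @param alpha reference spacing ratio in (0, 0.5]; `alpha = 0` is
#'   accepted to express the single-reference limit.
#' @return object of class `accuracy_model` with `mu = (mu1, mu2, mu3)`.
#' @export
accuracy_model <- function(m = 1023, sigma = 123, alpha = 1 / 3) {
  if (!is_number(sigma) || sigma <= 0) abort_oct("sigma must be > 0", "octmoco_value")
  if (!is_number(alpha) || alpha < 0 || alpha > 0.5)
    abort_oct("alpha must be in [0, 0.5]", "octmoco_value")
  mu <- c((0.5 - alpha) * m, m / 2, (0.5 + alpha) * m)
  structure(list(m = m, sigma = sigma, alpha = alpha, mu = mu),
            class = "accuracy_model")
}

#' Per-reference Gaussian accuracy
#'
#' `R(x; mu, sigma) = exp(-(x - mu)^2 / (2 sigma^2))`, peak-normalized
#' so the range is `[0, 1]`.
#'
#' @param x A-scan index (vectorized).
#' @param mu reference location.
#' @param sigma width.
#' @export
accuracy_R <- function(x, mu, sigma) {
  if (sigma <= 0) abort_oct("sigma must be > 0", "octmoco_value")
  exp(-(x - mu)^2 / (2 * sigma^2))
}

#' Combined accuracy of several references
#'
#' Inverse-distance weighted mixture
#' `Y(x) = sum_i w_i(x) R_i(x) / sum_i w_i(x)` with
#' `w_i(x) = 1 / (|x - mu_i| + 1)`; the `+ 1` avoids division by zero
#' at the reference columns.  As a convex combination of values in
#' `[0, 1]`, Y itself stays in `[0, 1]`, and when all `mu_i` coincide
#' (`alpha -> 0`) Y collapses to the single Gaussian.
#'
#' @param x A-scan index (vectorized).
#' @param model `accuracy_model`.
#' @export
combined_Y <- function(x, model) {
  W <- sapply(model$mu, function(mu) 1 / (abs(x - mu) + 1))
  R <- sapply(model$mu, function(mu) accuracy_R(x, mu, model$sigma))
  if (length(x) == 1L) { W <- matrix(W, nrow = 1); R <- matrix(R, nrow = 1) }
  rowSums(W * R) / rowSums(W)
}

#' Placement error functional
#'
#' `E(alpha, sigma) = sum_{x = 0}^{m} [1 - Y(x)]` over integer A-scan
#' indices.
#'
#' @param alpha spacing ratio.
#' @param sigma Gaussian width.
#' @param m maximum A-scan index.
#' @export
error_E <- function(alpha, sigma, m = 1023) {
  model <- accuracy_model(m = m, sigma = sigma, alpha = alpha)
  sum(1 - combined_Y(0:m, model))
}

#' Optimal spacing ratio by grid search
#'
#' Minimizes `E(alpha, sigma)` over the grid
#' `alpha = grid_step, 2 grid_step, ..., <= 0.5`; ties go to the
#' smaller alpha.  The default step 10/1024 is the granularity used
#' when the theory was matched against experiment; pass a finer step
#' for a sharper argmin (the functional is nearly flat within about
#' 0.005 of its minimum).
#'
#' @param sigma Gaussian width.
#' @param m maximum A-scan index.
#' @param grid_step alpha grid step.
#' @return list with `alpha` (argmin), `E` (its value), and the full
#'   `grid` data.frame.
#' @export
optimal_alpha <- function(sigma, m = 1023, grid_step = 10 / 1024) {
  if (!is_number(grid_step) || grid_step <= 0)
    abort_oct("grid_step must be > 0", "octmoco_value")
  alphas <- seq(grid_step, 0.5, by = grid_step)
  x <- 0:m
  Ev <- vapply(alphas, function(a) {
    model <- accuracy_model(m = m, sigma = sigma, alpha = a)
    sum(1 - combined_Y(x, model))
  }, numeric(1))
  # ties -> smaller alpha; "tie" means equal within a flatness
  # tolerance of 1e-8 per summed A-scan, so degenerate landscapes
  # (sigma >> m, where E is uniformly ~0) resolve to the smallest grid
  # point without disturbing the argmin of any non-degenerate curve
  tol <- (m + 1) * 1e-8
  k <- which(Ev <= min(Ev) + tol)[1]
  list(alpha = alphas[k], E = Ev[k],
       grid = data.frame(alpha = alphas, E = Ev))
}

#' Fit the Gaussian width to an empirical error curve
#'
#' Finds sigma minimizing
#' `W(sigma) = (1/s) sum_i |E(alpha_i, sigma) - Expr(alpha_i)|`
#' over a sigma grid.  Both curves are min-max normalized to `[0, 1]`
#' before comparison by default (the empirical curves this is meant
#' for are reported in normalized form); set `normalize = FALSE` for
#' raw comparison.
#'
#' @param empirical data.frame with columns `alpha` and `error`.
#' @param m maximum A-scan index.
#' @param sigma_grid candidate sigmas (default 1..400).
#' @param normalize min-max normalize both curves first.
#' @return list with `sigma` (argmin), `W` (its value), and the full
#'   `grid` data.frame.
#' @export
fit_sigma <- function(empirical, m = 1023, sigma_grid = 1:400,
                      normalize = TRUE) {
  if (is.null(empirical$alpha) || is.null(empirical$error) ||
      nrow(empirical) < 3L)
    abort_oct("empirical curve needs >= 3 (alpha, error) points",
              "octmoco_value")
  norm01 <- function(v) {
    r <- range(v)
    if (r[2] > r[1]) (v - r[1]) / (r[2] - r[1]) else v * 0
  }
  target <- if (normalize) norm01(empirical$error) else empirical$error
  x <- 0:m
  Wv <- vapply(sigma_grid, function(s) {
    Ev <- vapply(empirical$alpha, function(a) {
      model <- accuracy_model(m = m, sigma = s, alpha = a)
      sum(1 - combined_Y(x, model))
    }, numeric(1))
    if (normalize) Ev <- norm01(Ev)
    mean(abs(Ev - target))
  }, numeric(1))
  k <- which.min(Wv)
  list(sigma = sigma_grid[k], W = Wv[k],
       grid = data.frame(sigma = sigma_grid, W = Wv))
}

#' Evenly-distributed reference plane positions
#'
#' With t planes over a B-scan of width L, the i'th plane sits at
#' `(2i - 1) L / (2t)` — the rule that minimizes the placement error.
#'
#' @param t number of planes (>= 1).
#' @param L B-scan width.
#' @return numeric vector of t positions.
#' @export
plane_positions <- function(t, L) {
  if (!is_count(t)) abort_oct("t must be a positive integer", "octmoco_value")
  (2 * seq_len(t) - 1) * L / (2 * t)
}
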