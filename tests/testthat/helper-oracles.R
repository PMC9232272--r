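# Independent brute-force oracles used to check the implementation.
# These deliberately share no code with the package internals.

# direct double-loop same-size correlation with replicate padding,
# anchor at floor(k/2) (0-based)
oracle_filter2 <- function(img, kernel) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- nrow(kernel); kc <- ncol(kernel)
  ca <- kr %/% 2; cb <- kc %/% 2
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (a in seq_len(kr)) for (b in seq_len(kc)) {
      ii <- min(max(i + a - 1 - ca, 1), nr)
      jj <- min(max(j + b - 1 - cb, 1), nc)
      acc <- acc + kernel[a, b] * img[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# per-column moving-average subtraction oracle (40x1 kernel semantics)
oracle_remove_sat <- function(img, len) {
  A <- matrix(1 / len, nrow = len, ncol = 1)
  img - oracle_filter2(img, A)
}

# BFS 8-connected labelling oracle
oracle_label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue[[length(queue) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# exhaustive lateral-shift scan oracle on the Eq.-(5) style cost
oracle_lateral <- function(z_t, z_1, search) {
  best <- NULL
  for (dl in -search:search) {
    lo <- max(ceiling(z_1$domain[1]), ceiling(z_t$domain[1] - dl))
    hi <- min(floor(z_1$domain[2]), floor(z_t$domain[2] - dl))
    if (hi - lo + 1 < 10) next
    x <- lo:hi
    cost <- stats::var(abs(poly_eval(z_t, x + dl) - poly_eval(z_1, x)))
    if (is.null(best) || cost < best$cost - 1e-15 ||
        (abs(cost - best$cost) <= 1e-15 &&
         (abs(dl) < abs(best$dl) ||
          (abs(dl) == abs(best$dl) && dl < best$dl)))) {
      best <- list(dl = dl, cost = cost)
    }
  }
  best
}

# Lagrange interpolation oracle
oracle_lagrange <- function(x0, y0, x) {
  out <- numeric(length(x))
  for (i in seq_along(x0)) {
    li <- rep(1, length(x))
    for (j in seq_along(x0)) {
      if (j != i) li <- li * (x - x0[j]) / (x0[i] - x0[j])
    }
    out <- out + y0[i] * li
  }
  out
}

# small standard protocol for fast simulation tests: 192 x 96 x 64
# voxels, threshold window shrunk to fit the 64-column references
test_protocol <- function(n_slow = 64L, n_refs = 3L, alpha = 0.33) {
  scan_protocol(n_depth = 192L, n_fast = 96L, n_slow = n_slow,
                axial_pitch_um = 3.6, fast_pitch_um = 10000 / 96,
                slow_pitch_um = 11000 / 64, bscan_rate_hz = 100,
                n_refs = n_refs, alpha = alpha)
}

test_preprocess_config <- function(...) {
  preprocess_config(threshold_window = 32L, border_crop = 5L, ...)
}

test_phantom <- function(p, ...) {
  phantom_surface(p, "quartic", apex_depth_px = 80, ...)
}
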