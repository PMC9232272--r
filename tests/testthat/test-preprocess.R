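test_that("filtering operations match the brute-force convolution oracle", {
  set.seed(11)
  img <- matrix(rnorm(48 * 40), 48, 40)
  cfg <- preprocess_config()
  # generic correlation: random 5x3 kernel
  k <- matrix(rnorm(15), 5, 3)
  expect_lt(max(abs(filter2_replicate(img, k) - oracle_filter2(img, k))), 1e-10)
  # Gaussian smoothing equals the full 10x10 kernel correlation
  g1 <- exp(-((1:10) - 5.5)^2 / (2 * 16))
  K <- outer(g1, g1); K <- K / sum(K)
  expect_lt(max(abs(gaussian_smooth(img, cfg) - oracle_filter2(img, K))), 1e-10)
  # saturation removal equals the 40x1 moving-average subtraction
  expect_lt(max(abs(remove_saturation(img, cfg) -
                      oracle_remove_sat(img, 40))), 1e-10)
  # impulse response of the smoother equals the kernel itself (interior)
  imp <- matrix(0, 30, 30); imp[15, 16] <- 1
  sm <- gaussian_smooth(imp, cfg)
  expect_lt(max(abs(sm[11:20, 12:21] - K[10:1, 10:1])), 1e-12)
})

test_that("gaussian_smooth is linear and preserves constants", {
  cfg <- preprocess_config()
  expect_equal(gaussian_smooth(matrix(7, 25, 30), cfg), matrix(7, 25, 30),
               tolerance = 1e-12)
  set.seed(12)
  A <- matrix(rnorm(300), 20, 15); B <- matrix(rnorm(300), 20, 15)
  expect_equal(gaussian_smooth(2 * A - 3 * B, cfg),
               2 * gaussian_smooth(A, cfg) - 3 * gaussian_smooth(B, cfg),
               tolerance = 1e-10)
  expect_error(gaussian_smooth(1:10, cfg), class = "octmoco_shape")
})

test_that("remove_saturation zeroes constants and depth-constant stripes", {
  cfg <- preprocess_config()
  expect_lt(max(abs(remove_saturation(matrix(5, 60, 20), cfg))), 1e-12)
  set.seed(13)
  img <- matrix(rnorm(60 * 20), 60, 20)
  img2 <- img; img2[, 7] <- img2[, 7] + 42   # depth-constant stripe
  expect_lt(max(abs(remove_saturation(img2, cfg)[, 7] -
                      remove_saturation(img, cfg)[, 7])), 1e-10)
  expect_error(remove_saturation(matrix(0, 39, 10), cfg),
               class = "octmoco_shape")
})

test_that("adaptive_threshold separates a band and rejects degenerates", {
  cfg <- preprocess_config(threshold_window = 16L)
  img <- matrix(0, 64, 48)
  img[30:33, ] <- 10
  m <- adaptive_threshold(img, cfg)
  expect_true(all(m[30:33, ]))
  expect_false(any(m[-(30:33), ]))
  # constant image: nothing strictly exceeds its own local mean
  expect_false(any(adaptive_threshold(matrix(3, 64, 48), cfg)))
  expect_error(adaptive_threshold(matrix(1, 8, 8), cfg),
               class = "octmoco_shape")
})

test_that("largest_component matches the BFS oracle and honours ties", {
  set.seed(14)
  for (rep in 1:5) {
    mask <- matrix(runif(32 * 32) < 0.35, 32, 32)
    if (!any(mask)) next
    lab <- oracle_label8(mask)
    sizes <- tabulate(lab[lab > 0])
    keep <- largest_component(mask)
    expect_equal(sum(keep), max(sizes))
    # the kept set is exactly one oracle component
    ids <- unique(lab[keep])
    expect_length(ids, 1L)
    expect_equal(sum(lab == ids), max(sizes))
  }
  # two blobs of different sizes: only the big one survives
  mask <- matrix(FALSE, 20, 20)
  mask[2:11, 2:11] <- TRUE            # 100 px
  mask[15:16, 15:19] <- TRUE          # 10 px
  expect_equal(which(largest_component(mask)), which({
    m <- matrix(FALSE, 20, 20); m[2:11, 2:11] <- TRUE; m
  }))
  # single component unchanged
  expect_equal(largest_component(mask & !{
    m <- matrix(FALSE, 20, 20); m[15:16, 15:19] <- TRUE; m
  }), {
    m <- matrix(FALSE, 20, 20); m[2:11, 2:11] <- TRUE; m
  })
  # tie broken by brightest source pixel
  mask <- matrix(FALSE, 10, 10)
  mask[2:3, 2:3] <- TRUE; mask[7:8, 7:8] <- TRUE
  bright <- matrix(0, 10, 10); bright[7, 7] <- 5
  keep <- largest_component(mask, bright)
  expect_true(keep[7, 7]); expect_false(keep[2, 2])
  expect_error(largest_component(matrix(FALSE, 5, 5)),
               class = "octmoco_no_surface")
})

test_that("initial_surface takes the shallowest pixel and interpolates gaps", {
  comp <- matrix(FALSE, 50, 30)
  comp[21, ] <- TRUE                 # flat band at depth 20 (0-based)
  tr <- initial_surface(comp)
  expect_equal(tr$depths, rep(20, 30))
  expect_true(all(tr$valid))
  # 5-column gap -> linear interpolation, flagged invalid
  comp2 <- matrix(FALSE, 50, 30)
  comp2[11, 1:10] <- TRUE
  comp2[21, 16:30] <- TRUE
  tr2 <- initial_surface(comp2)
  expect_false(any(tr2$valid[11:15]))
  expect_equal(tr2$depths[11:15], 10 + (1:5) * (20 - 10) / 6)
  # edge columns take the nearest valid value
  comp3 <- matrix(FALSE, 50, 30)
  comp3[31, 5:30] <- TRUE
  expect_equal(initial_surface(comp3)$depths[1:4], rep(30, 4))
  expect_error(initial_surface(matrix(FALSE, 5, 5)),
               class = "octmoco_no_surface")
})

test_that("gradient_image matches a hand-convolved oracle and is non-negative", {
  cfg <- preprocess_config()
  expect_equal(gradient_image(matrix(4, 20, 20), cfg), matrix(0, 20, 20))
  set.seed(15)
  img <- matrix(rnorm(30 * 25), 30, 25)
  S <- matrix(c(1, 2, 1, 0, 0, 0, -1, -2, -1), 3, 3, byrow = TRUE)
  P <- matrix(c(1, 1, 1, 0, 0, 0, -1, -1, -1), 3, 3, byrow = TRUE)
  Fo <- oracle_filter2(img, S)^2 + oracle_filter2(img, P)^2
  expect_lt(max(abs(gradient_image(img, cfg) - Fo)), 1e-9)
  expect_true(all(gradient_image(img, cfg) >= 0))
  # vertical (depth) step edge: gradient peaks on the edge rows
  step <- rbind(matrix(1, 10, 9), matrix(0, 10, 9))
  Fs <- gradient_image(step, cfg)
  expect_lt(max(abs(Fs - (oracle_filter2(step, S)^2 +
                            oracle_filter2(step, P)^2))), 1e-12)
  expect_true(which.max(Fs[, 5]) %in% 10:11)
  # sqrt variant preserves ranking
  cfg2 <- preprocess_config(gradient_sqrt = TRUE)
  expect_equal(gradient_image(img, cfg2)^2, gradient_image(img, cfg),
               tolerance = 1e-9)
})

test_that("refine_surface scans the window exhaustively with stated ties", {
  cfg <- preprocess_config(refine_window = 15L)
  nr <- 60; nc <- 12
  # unique max at +7 px offset in every column
  Fm <- matrix(0, nr, nc)
  init <- surface_trace(rep(25, nc))
  for (j in seq_len(nc)) Fm[25 + 7 + 1, j] <- 5
  expect_equal(refine_surface(init, Fm, cfg)$depths, rep(32, nc))
  # max exactly at the trace -> unchanged
  Fm2 <- matrix(0, nr, nc); Fm2[26, ] <- 3
  expect_equal(refine_surface(init, Fm2, cfg)$depths, rep(25, nc))
  # all-flat gradient: tie resolves to the initial depth
  expect_equal(refine_surface(init, matrix(1, nr, nc), cfg)$depths,
               rep(25, nc))
  # symmetric tie at +-4: closest tie -> shallower wins
  Fm3 <- matrix(0, nr, nc); Fm3[22, ] <- 2; Fm3[30, ] <- 2
  expect_equal(refine_surface(init, Fm3, cfg)$depths, rep(21, nc))
  # window clipped at the image top
  init2 <- surface_trace(rep(3, nc))
  Fm4 <- matrix(0, nr, nc); Fm4[1, ] <- 9   # row 0 within clipped window
  expect_equal(refine_surface(init2, Fm4, cfg)$depths, rep(0, nc))
  expect_error(refine_surface(surface_trace(rep(1, 5)), Fm, cfg),
               class = "octmoco_shape")
})

test_that("fit_surface solves least squares exactly where it should", {
  x <- 0:20
  cf <- c(2, -0.5, 0.03, -0.002, 0.0001)   # ascending quartic
  z <- cf[1] + cf[2] * x + cf[3] * x^2 + cf[4] * x^3 + cf[5] * x^4
  ps <- fit_surface(surface_trace(z), 4)
  expect_equal(ps$coeffs, cf, tolerance = 1e-8)
  expect_equal(ps$domain, c(0, 20))
  # constant trace
  ps0 <- fit_surface(surface_trace(rep(7, 12)), 4)
  expect_equal(ps0$coeffs[1], 7, tolerance = 1e-10)
  expect_lt(max(abs(ps0$coeffs[-1])), 1e-10)
  # 12-point noisy instance vs direct normal equations on the raw
  # Vandermonde system (small x keeps it well conditioned)
  set.seed(16)
  x12 <- 0:11
  z12 <- 3 + 0.2 * x12 - 0.05 * x12^2 + rnorm(12, sd = 0.3)
  V <- outer(x12, 0:3, `^`)
  beta <- solve(t(V) %*% V, t(V) %*% z12)
  ps3 <- fit_surface(surface_trace(z12), 3)
  expect_equal(as.numeric(ps3$coeffs), as.numeric(beta), tolerance = 1e-9)
  # only valid columns participate
  zv <- c(z12, 1e6)
  psv <- fit_surface(surface_trace(zv, c(rep(TRUE, 12), FALSE)), 3)
  expect_equal(psv$coeffs, ps3$coeffs, tolerance = 1e-9)
  expect_error(fit_surface(surface_trace(1:4), 4), class = "octmoco_rank")
})

test_that("fit residual is non-increasing in polynomial order", {
  set.seed(17)
  z <- 50 + 0.1 * (0:63) + sin((0:63) / 9) * 3 + rnorm(64, sd = 0.5)
  tr <- surface_trace(z)
  res <- vapply(2:6, function(n) fit_residual_rms(fit_surface(tr, n), tr),
                numeric(1))
  expect_true(all(diff(res) <= 1e-9))
})

test_that("preprocess_bscan recovers simulator surfaces", {
  p <- test_protocol()
  surf <- test_phantom(p)
  cfg <- test_preprocess_config()
  zt <- surface_depth_px(surf, 0:(p$n_fast - 1), 10)
  # noise-free: fit within 0.5 px RMS of the true surface
  b0 <- render_bscan(surf, list(axis = "fast", at = 10),
                     noise = noise_config(speckle = FALSE), seed = 1)
  f0 <- preprocess_bscan(b0, cfg)$fit
  expect_lt(sqrt(mean((poly_eval(f0, 0:(p$n_fast - 1)) - zt)^2)), 0.5)
  # >= 99% of columns within 1 px on noise-free frames
  expect_gte(mean(abs(poly_eval(f0, 0:(p$n_fast - 1)) - zt) <= 1), 0.99)
  # saturation stripes do not degrade the fit by more than 2x
  bs <- render_bscan(surf, list(axis = "fast", at = 10),
                     noise = noise_config(speckle = TRUE), seed = 5)
  bss <- render_bscan(surf, list(axis = "fast", at = 10),
                      noise = noise_config(speckle = TRUE,
                                           saturation_stripes = 4L), seed = 5)
  e1 <- mean(abs(poly_eval(preprocess_bscan(bs, cfg)$fit,
                           0:(p$n_fast - 1)) - zt))
  e2 <- mean(abs(poly_eval(preprocess_bscan(bss, cfg)$fit,
                           0:(p$n_fast - 1)) - zt))
  expect_lt(e2, 2 * max(e1, 0.5))
  # surface band is the largest bright component on simulator output
  sm <- gaussian_smooth(bs$pixels, cfg)
  sat <- remove_saturation(sm, cfg)
  comp <- largest_component(adaptive_threshold(sat, cfg), sat)
  rows <- which(comp, arr.ind = TRUE)[, 1] - 1
  expect_true(all(abs(rows - zt[which(comp, arr.ind = TRUE)[, 2]]) < 12))
  # pure noise, no surface: classified as segmentation failure
  noise_img <- matrix(stats::rexp(192 * 96) * 1e-3, 192, 96)
  expect_error(preprocess_bscan(bscan(noise_img, "fast"), cfg),
               class = "octmoco_no_surface")
})
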