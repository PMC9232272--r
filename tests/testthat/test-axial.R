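test_that("reference_depths_at evaluates reference fits with domain checks", {
  flat <- lapply(1:3, function(i) poly_surface(200, c(0, 63)))
  rs <- reference_set(vector("list", 3), ref_fits = flat, ref_x = c(10, 32, 53))
  expect_equal(reference_depths_at(rs, 17), c(200, 200, 200))
  # quartic fits vs direct polynomial evaluation
  cf <- c(150, 0.5, -0.01, 1e-4, -5e-7)
  qs <- lapply(1:3, function(i) poly_surface(cf * i, c(0, 63)))
  rs2 <- reference_set(vector("list", 3), ref_fits = qs, ref_x = c(10, 32, 53))
  y <- 25.5
  expect_equal(reference_depths_at(rs2, y),
               vapply(1:3, function(i) sum(cf * i * y^(0:4)), numeric(1)),
               tolerance = 1e-12)
  expect_error(reference_depths_at(rs2, 70), class = "octmoco_domain")
  expect_error(reference_depths_at(reference_set(vector("list", 3),
                                                 ref_x = c(1, 2, 3)), 1),
               class = "octmoco_value")
})

test_that("axial_offsets implements z_t(x_i^r) - z_i^r", {
  truth <- poly_surface(c(100, 0.2, -1e-3), c(0, 95))
  refs <- lapply(c(20, 48, 76), function(xr)
    poly_surface(poly_eval(truth, xr), c(0, 63)))   # flat in y at truth depth
  rs <- reference_set(vector("list", 3), ref_fits = refs, ref_x = c(20, 48, 76))
  expect_equal(axial_offsets(truth, rs, 10), c(0, 0, 0))
  shifted <- poly_surface(truth$coeffs + c(17, 0, 0), truth$domain)
  expect_equal(axial_offsets(shifted, rs, 10), c(17, 17, 17))
  tilted <- poly_surface(truth$coeffs + c(3, 0.1, 0), truth$domain)
  expect_equal(axial_offsets(tilted, rs, 10), 3 + 0.1 * c(20, 48, 76))
})

test_that("fit_axial_motion interpolates exactly (Lagrange oracle)", {
  set.seed(31)
  for (rep in 1:10) {
    x <- sort(sample(0:1023, 3))
    a <- rnorm(3, sd = 50)
    m <- fit_axial_motion(x, a)
    # exact interpolation through the defining points
    expect_lt(max(abs(eval_axial(m, x) - a)), 1e-9)
    # agrees with the Lagrange form on 100 probe points
    xp <- seq(0, 1023, length.out = 100)
    expect_lt(max(abs(eval_axial(m, xp) - oracle_lagrange(x, a, xp))), 1e-9)
  }
  # constant offsets -> constant polynomial
  mc <- fit_axial_motion(c(100, 500, 900), c(4, 4, 4))
  expect_equal(mc$coeffs[1], 4, tolerance = 1e-10)
  expect_lt(max(abs(mc$coeffs[-1])), 1e-10)
  # collinear offsets -> zero curvature
  ml <- fit_axial_motion(c(100, 500, 900), c(1, 5, 9))
  expect_lt(abs(ml$coeffs[3]), 1e-9)
  # two points give the linear model used with two reference planes
  m2 <- fit_axial_motion(c(64, 192), c(2, 6))
  expect_equal(eval_axial(m2, c(64, 192)), c(2, 6), tolerance = 1e-10)
  expect_error(fit_axial_motion(c(1, 1, 2), c(0, 0, 0)),
               class = "octmoco_value")
})

test_that("compensate_axial shifts columns and keeps fractional surfaces", {
  px <- matrix(rep(1:40, 8), 40, 8)
  b <- bscan(px, "fast")
  z <- poly_surface(c(20, 0.1), c(0, 7))
  m0 <- fit_axial_motion(c(1, 4, 7), c(0, 0, 0))
  r0 <- compensate_axial(b, z, m0)
  expect_equal(r0$bscan$pixels, px)
  expect_equal(poly_eval(r0$surface, 0:7), poly_eval(z, 0:7))
  # constant +10 motion: columns shift up 10 px, f = z - 10
  m10 <- fit_axial_motion(c(1, 4, 7), c(10, 10, 10))
  r10 <- compensate_axial(b, z, m10)
  expect_equal(r10$bscan$pixels[1:30, ], px[11:40, ])
  expect_equal(r10$bscan$pixels[31:40, ], matrix(0, 10, 8))
  expect_equal(poly_eval(r10$surface, 3), poly_eval(z, 3) - 10)
  # fractional model: image shifts by round(a), surface stays exact
  mf <- fit_axial_motion(c(1, 4, 7), c(2.4, 2.4, 2.4))
  rf <- compensate_axial(b, z, mf)
  expect_equal(rf$bscan$pixels[1, 1], px[3, 1])
  expect_equal(poly_eval(rf$surface, 5), poly_eval(z, 5) - 2.4)
  mbig <- fit_axial_motion(c(1, 4, 7), c(100, 100, 100))
  expect_error(compensate_axial(b, z, mbig), class = "octmoco_value")
})

test_that("compensation recovers injected axial motion on simulator volumes", {
  p <- test_protocol(n_slow = 48L)
  surf <- test_phantom(p, ripple_amp_um = 4)
  mo <- make_motion("sinusoid",
                    list(axial = list(amp_um = 150, freq_hz = 2)),
                    frames = p$n_refs + p$n_slow, rate = p$bscan_rate_hz)
  sim <- simulate_acquisition(p, surf, mo, noise_config(speckle = FALSE),
                              seed = 77, render_static = FALSE,
                              intra_frame = FALSE)
  cfg <- compensate_config(preprocess = test_preprocess_config(),
                           search_px = 20L, crop_px = 5L)
  res <- compensate_volume(sim$volume, cfg)
  expect_equal(res$report$n_failed, 0L)
  # recovered per-frame axial offset at the middle reference ~ truth
  mid <- res$motion$ref_offset2
  expect_lt(mean(abs(mid - sim$truth$axial_px)), 1)
  # compensated surfaces near the analytic truth
  zt <- sim$truth$z_true[, 6:(p$n_fast - 5)]
  expect_lt(surface_error(res$surfaces, zt, p$axial_pitch_um)$mae_um /
              p$axial_pitch_um, 1.5)
})

test_that("compensation is a no-op on static volumes and is idempotent", {
  p <- test_protocol(n_slow = 48L)
  surf <- test_phantom(p, ripple_amp_um = 4)
  mo0 <- make_motion("sinusoid", list(), frames = p$n_refs + p$n_slow,
                     rate = p$bscan_rate_hz)
  sim <- simulate_acquisition(p, surf, mo0, noise_config(), seed = 99,
                              render_static = FALSE)
  cfg <- compensate_config(preprocess = test_preprocess_config(),
                           search_px = 20L, crop_px = 5L)
  res <- compensate_volume(sim$volume, cfg)
  pre <- volume_surfaces(sim$volume, cfg)
  # static input: compensated surfaces equal raw surfaces within 1 px
  expect_lt(mean(abs(res$surfaces - pre)), 1)
  # idempotence: compensating the compensated volume changes little
  res2 <- compensate_volume(res$volume, cfg)
  cols2 <- (cfg$crop_px + 1):(ncol(res$surfaces) - cfg$crop_px)
  expect_lt(mean(abs(res2$surfaces - res$surfaces[, cols2])), 1)
})
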