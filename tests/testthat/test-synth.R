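test_that("make_motion produces the stated sinusoids", {
  mo <- make_motion("sinusoid",
                    list(axial = list(amp_um = 700, freq_hz = 1)),
                    frames = 200, rate = 100)
  expect_equal(max(mo$axial_um), 700, tolerance = 1e-3)
  expect_equal(min(mo$axial_um), -700, tolerance = 1e-3)
  # period of 100 frames at 1 Hz / 100 Hz
  expect_equal(mo$axial_um[1:100], mo$axial_um[101:200], tolerance = 1e-9)
  expect_equal(mo$lateral_um, rep(0, 200))
  # zero amplitude -> all-zero trace
  mo0 <- make_motion("sinusoid", list(axial = list(amp_um = 0, freq_hz = 3)),
                     frames = 50, rate = 100)
  expect_equal(mo0$axial_um, rep(0, 50))
  expect_error(make_motion("sinusoid",
                           list(axial = list(amp_um = 1, freq_hz = 60)),
                           frames = 10, rate = 100),
               class = "octmoco_value")
})

test_that("freehand traces hit their step targets and stay band-limited", {
  for (s in 1:5) {
    mo <- make_motion("freehand",
                      list(axial = list(step_um = 14.18),
                           lateral = list(step_um = 165)),
                      frames = 131, rate = 100, seed = s)
    expect_equal(mean(abs(diff(mo$axial_um))), 14.18, tolerance = 0.1)
    expect_equal(mean(abs(diff(mo$lateral_um))), 165, tolerance = 0.1)
    # anchored to the start pose
    expect_equal(mo$axial_um[1], 0, tolerance = 1e-9)
  }
  # band-limitation, measured on a long (10 s) trace so the DFT can
  # resolve the band edge: >= 95% of energy below 5 Hz plus two bins,
  # < 1% above 15 Hz
  for (s in 1:5) {
    mo <- make_motion("freehand",
                      list(axial = list(step_um = 14.18),
                           lateral = list(step_um = 165)),
                      frames = 1024, rate = 100, seed = s)
    sp <- motion_spectrum(mo, rate = 100)
    edge <- 5 + 2 * 100 / 1024
    expect_gte(sp$energy_below(edge, "axial"), 0.95)
    expect_gte(sp$energy_below(edge, "lateral"), 0.95)
    expect_lt(1 - sp$energy_below(15, "axial"), 0.01)
    expect_lt(1 - sp$energy_below(15, "lateral"), 0.01)
  }
  # deterministic per seed
  m1 <- make_motion("freehand", list(axial = list(step_um = 10)),
                    frames = 64, rate = 100, seed = 7)
  m2 <- make_motion("freehand", list(axial = list(step_um = 10)),
                    frames = 64, rate = 100, seed = 7)
  expect_identical(m1$axial_um, m2$axial_um)
})

test_that("render_bscan draws the band where the surface is", {
  p <- test_protocol(n_slow = 8L)
  surf <- test_phantom(p)
  b <- render_bscan(surf, list(axis = "fast", at = 3),
                    noise = noise_config(speckle = FALSE), seed = 1)
  zt <- surface_depth_px(surf, 0:(p$n_fast - 1), 3)
  peaks <- apply(b$pixels, 2, which.max) - 1
  expect_true(all(abs(peaks - round(zt)) <= 1))
  # +50 px axial offset moves the band 50 px deeper
  b50 <- render_bscan(surf, list(axis = "fast", at = 3), offsets = c(50, 0),
                      noise = noise_config(speckle = FALSE), seed = 1)
  expect_equal(b50$pixels[51:nrow(b50$pixels), ],
               b$pixels[1:(nrow(b$pixels) - 50), ], tolerance = 1e-9)
  # determinism: same seed, bit-identical
  r1 <- render_bscan(surf, list(axis = "fast", at = 3), noise = noise_config(),
                     seed = 9)
  r2 <- render_bscan(surf, list(axis = "fast", at = 3), noise = noise_config(),
                     seed = 9)
  expect_identical(r1$pixels, r2$pixels)
  # surface out of depth range is refused
  deep <- phantom_surface(p, "quartic", apex_depth_px = p$n_depth - 5)
  expect_error(render_bscan(deep, list(axis = "fast", at = 3)),
               class = "octmoco_value")
})

test_that("saturation stripes appear as seeded full-depth columns", {
  p <- test_protocol(n_slow = 8L)
  surf <- test_phantom(p)
  nz <- noise_config(speckle = FALSE, saturation_stripes = 3L)
  b <- render_bscan(surf, list(axis = "fast", at = 2), noise = nz, seed = 4)
  b0 <- render_bscan(surf, list(axis = "fast", at = 2),
                     noise = noise_config(speckle = FALSE), seed = 4)
  d <- b$pixels - b0$pixels
  stripe_cols <- which(colSums(d > 0) == nrow(d))
  expect_length(stripe_cols, 3L)
  expect_true(all(d[, stripe_cols] == nz$saturation_intensity))
})

test_that("simulate_acquisition follows the scanning protocol", {
  p <- test_protocol(n_slow = 16L)
  surf <- test_phantom(p)
  mo <- make_motion("sinusoid", list(axial = list(amp_um = 80, freq_hz = 2)),
                    frames = p$n_refs + p$n_slow, rate = p$bscan_rate_hz)
  sim <- simulate_acquisition(p, surf, mo, noise_config(), seed = 5)
  expect_length(sim$volume$references$ref_bscans, 3L)
  expect_length(sim$volume$bscans, 16L)
  expect_equal(sim$volume$references$ref_bscans[[2]]$slow_position,
               p$ref_positions[2])
  # references are slow-axis frames of n_slow columns
  expect_equal(dim(sim$volume$references$ref_bscans[[1]]$pixels),
               c(p$n_depth, p$n_slow))
  # frozen references: identical to a zero-offset render with their seed
  ref1 <- render_bscan(surf, list(axis = "slow", at = p$ref_positions[1],
                                  index = 0L),
                       noise = noise_config(), seed = octmoco:::derive_seed(5, 0))
  expect_identical(sim$volume$references$ref_bscans[[1]]$pixels, ref1$pixels)
  # ground-truth motion-free twin equals a zero-trace run, same seed
  mo0 <- make_motion("sinusoid", list(), frames = p$n_refs + p$n_slow,
                     rate = p$bscan_rate_hz)
  sim0 <- simulate_acquisition(p, surf, mo0, noise_config(), seed = 5)
  for (j in c(1L, 7L, 16L))
    expect_identical(sim$truth$static_volume$bscans[[j]]$pixels,
                     sim0$volume$bscans[[j]]$pixels)
  # full determinism of the volume
  simb <- simulate_acquisition(p, surf, mo, noise_config(), seed = 5)
  expect_identical(sim$volume$bscans[[9]]$pixels, simb$volume$bscans[[9]]$pixels)
  # trace too short
  expect_error(simulate_acquisition(p, surf,
                                    make_motion("sinusoid", list(), frames = 4),
                                    noise_config(), seed = 1),
               class = "octmoco_value")
})

test_that("peak detection on noise-free renders recovers z_true everywhere", {
  p <- test_protocol(n_slow = 8L)
  for (kind in c("quartic", "spherical_cap", "keratoconus")) {
    surf <- phantom_surface(p, kind, apex_depth_px = 80)
    b <- render_bscan(surf, list(axis = "slow", at = 40),
                      noise = noise_config(speckle = FALSE), seed = 2)
    zt <- surface_depth_px(surf, 40, 0:(p$n_slow - 1))
    peaks <- apply(b$pixels, 2, which.max) - 1
    expect_true(all(abs(peaks - zt) <= 1))
  }
})
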