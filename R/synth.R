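## Synthetic OCT acquisition simulator.
##
## Generates speckled B-scans of a smooth corneal phantom under seeded
## axial/lateral sample motion, following the same protocol as the real
## instrument: n_refs slow-axis reference B-scans first (motion-free by
## default, matching the method's stated assumption), then a raster
## C-scan of fast-axis frames.  Ground truth (analytic surface,
## per-frame offsets, and a motion-free twin volume rendered with the
## same per-frame noise seeds) is returned alongside.

#' Corneal phantom surface
#'
#' Analytic anterior surface `z_true(x, y)` in axial pixels, with x/y
#' in (possibly fractional) column/frame index units.  Kinds:
#' `"quartic"` — a gently aspheric cap
#' `z = z0 + (c2 r^2 + c4 r^4)` with r the lateral distance from the
#' apex in mm and the sag converted to pixels; `"spherical_cap"` — an
#' exact sphere of radius `radius_mm`; `"keratoconus"` — the quartic
#' cap plus a local Gaussian steepening bump.
#'
#' @param protocol `scan_protocol` (supplies the pixel pitches).
#' @param kind surface family.
#' @param apex_depth_px depth of the apex in pixels.
#' @param c2_um_mm2,c4_um_mm4 quartic sag coefficients (micrometers per
#'   mm^2 / mm^4).  Defaults give about 140 um of sag across a 1 cm
#'   field — a shallow shell, so that the full surface plus the motion
#'   amplitudes under study stays inside the imaging depth.
#' @param radius_mm sphere radius for `"spherical_cap"`.
#' @param bump_height_um,bump_width_mm,bump_center_mm keratoconus bump
#'   parameters (center is (x, y) offset from the apex in mm).
#' @param ripple_amp_um amplitude of a smooth sinusoidal surface
#'   irregularity added on top of `"quartic"`/`"keratoconus"` caps
#'   (default 0 = exact polynomial cap).  Real corneal and shell
#'   surfaces are not polynomial at the few-micrometer scale; the
#'   ripple is what makes the order-4 fit leave a smooth residual that
#'   the reference planes must track.
#' @param ripple_wavelength_mm lateral wavelength of the irregularity.
#' @param apex_xy optional apex position in (x, y) index units; default
#'   is the field center.
#' @return object of class `phantom_surface`; call it via
#'   [surface_depth_px()].
#' @export
phantom_surface <- function(protocol, kind = c("quartic", "spherical_cap",
                                               "keratoconus"),
                            apex_depth_px = 0.45 * protocol$n_depth,
                            c2_um_mm2 = 5.2, c4_um_mm4 = 0.012,
                            radius_mm = 86,
                            bump_height_um = 40, bump_width_mm = 0.8,
                            bump_center_mm = c(1.2, 0),
                            ripple_amp_um = 0, ripple_wavelength_mm = 6.5,
                            apex_xy = NULL) {
  kind <- match.arg(kind)
  if (is.null(apex_xy))
    apex_xy <- c((protocol$n_fast - 1) / 2, (protocol$n_slow - 1) / 2)
  obj <- structure(list(kind = kind, protocol = protocol,
                        apex_depth_px = apex_depth_px,
                        c2_um_mm2 = c2_um_mm2, c4_um_mm4 = c4_um_mm4,
                        radius_mm = radius_mm,
                        bump_height_um = bump_height_um,
                        bump_width_mm = bump_width_mm,
                        bump_center_mm = bump_center_mm,
                        ripple_amp_um = ripple_amp_um,
                        ripple_wavelength_mm = ripple_wavelength_mm,
                        apex_xy = apex_xy),
                   class = "phantom_surface")
  obj
}

#' Evaluate a phantom surface
#'
#' @param surface `phantom_surface`.
#' @param x,y positions in fast-column / slow-frame index units
#'   (vectorized, recycled).
#' @return depth in (fractional) pixels, 0-based.
#' @export
surface_depth_px <- function(surface, x, y) {
  p <- surface$protocol
  dx_mm <- (x - surface$apex_xy[1]) * p$fast_pitch_um / 1000
  dy_mm <- (y - surface$apex_xy[2]) * p$slow_pitch_um / 1000
  r2 <- dx_mm^2 + dy_mm^2
  sag_um <- switch(surface$kind,
    quartic = surface$c2_um_mm2 * r2 + surface$c4_um_mm4 * r2^2,
    spherical_cap = {
      R <- surface$radius_mm
      1000 * (R - sqrt(pmax(R^2 - r2, 0)))
    },
    keratoconus = {
      b <- surface$bump_center_mm
      rb2 <- (dx_mm - b[1])^2 + (dy_mm - b[2])^2
      surface$c2_um_mm2 * r2 + surface$c4_um_mm4 * r2^2 +
        surface$bump_height_um * exp(-rb2 / (2 * surface$bump_width_mm^2))
    })
  if (surface$ripple_amp_um > 0 && surface$kind != "spherical_cap") {
    lam <- surface$ripple_wavelength_mm
    sag_um <- sag_um + surface$ripple_amp_um *
      (sin(2 * pi * dx_mm / lam + 0.9) +
         0.6 * sin(2 * pi * dy_mm / (1.1 * lam) + 2.1))
  }
  surface$apex_depth_px + sag_um / p$axial_pitch_um
}

#' Noise configuration for rendered B-scans
#'
#' @param speckle multiply the signal by unit-mean exponential speckle
#'   (the fully-developed-speckle intensity model).
#' @param band_amplitude peak intensity of the surface band.
#' @param band_thickness_px axial extent of the bright surface band.
#' @param psf_sigma_px axial Gaussian blur of the band (1.5 px at
#'   3.6 um/px approximates the 4.5-6 um axial resolution).
#' @param background_level additive background intensity (default 0:
#'   OCT display floors the background; a nonzero level needs a
#'   positive `threshold_offset` downstream to keep the background out
#'   of the segmentation mask).
#' @param saturation_stripes number of full-depth saturated A-lines per
#'   frame, at seeded random columns.
#' @param saturation_intensity added intensity of a saturated stripe.
#' @export
noise_config <- function(speckle = TRUE, band_amplitude = 100,
                         band_thickness_px = 2, psf_sigma_px = 1.5,
                         background_level = 0,
                         saturation_stripes = 0L,
                         saturation_intensity = 150) {
  for (nm in c("band_amplitude", "band_thickness_px", "psf_sigma_px"))
    if (!is_number(get(nm)) || get(nm) <= 0)
      abort_oct(paste(nm, "must be > 0"), "octmoco_config")
  if (background_level < 0 || saturation_stripes < 0 || saturation_intensity < 0)
    abort_oct("noise parameters must be non-negative", "octmoco_config")
  structure(list(speckle = isTRUE(speckle), band_amplitude = band_amplitude,
                 band_thickness_px = band_thickness_px,
                 psf_sigma_px = psf_sigma_px,
                 background_level = background_level,
                 saturation_stripes = as.integer(saturation_stripes),
                 saturation_intensity = saturation_intensity),
            class = "noise_config")
}

#' Generate a per-frame motion trace
#'
#' `kind = "sinusoid"`: `A sin(2 pi f t + phase)` sampled at frame
#' times `t = index / rate`, separately for axial and lateral via
#' `params$axial` / `params$lateral` (each a list with `amp_um`,
#' `freq_hz`, optional `phase`; omit an axis for zero motion).
#'
#' `kind = "freehand"`: per axis, a sum of `n_components` (>= 8)
#' random-phase sinusoids with frequencies drawn below `f_max_hz`
#' (default 5 Hz), rescaled so the mean absolute inter-frame step
#' equals `step_um`, then anchored to zero displacement at t = 0 (the
#' pose the reference planes record).  `params$axial$step_um` and
#' `params$lateral$step_um` set the targets.
#'
#' @param kind `"sinusoid"` or `"freehand"`.
#' @param params nested list, see above.
#' @param frames total frame count (references + C-scan).
#' @param rate B-scan rate in Hz.
#' @param seed RNG seed (freehand only; sinusoids are deterministic).
#' @return object of class `motion_trace` with `times`, `axial_um`,
#'   `lateral_um`, `kind`, `seed`.
#' @export
make_motion <- function(kind = c("sinusoid", "freehand"), params = list(),
                        frames, rate = 100, seed = 1L) {
  kind <- match.arg(kind)
  if (!is_count(frames)) abort_oct("frames must be >= 1", "octmoco_value")
  times <- (seq_len(frames) - 1) / rate
  one_axis <- function(ax) {
    if (is.null(ax))
      return(list(samples = numeric(frames), fun = function(t) numeric(length(t))))
    if (kind == "sinusoid") {
      f <- ax$freq_hz %||% 1
      if (any(f >= rate / 2))
        abort_oct(sprintf("frequency %g Hz aliases at rate %g Hz", max(f), rate),
                  "octmoco_value")
      A <- ax$amp_um %||% 0
      ph <- ax$phase %||% 0
      n <- max(length(A), length(f), length(ph))   # multi-component sum
      A <- rep_len(A, n); f <- rep_len(f, n); ph <- rep_len(ph, n)
      fun <- function(t)
        colSums(A * sin(outer(2 * pi * f, t) + ph))
      list(samples = fun(times), fun = fun)
    } else {
      n <- ax$n_components %||% 8L
      if (n < 8L) n <- 8L
      fmax <- ax$f_max_hz %||% 5
      fmin <- ax$f_min_hz %||% 0.5
      if (fmax >= rate / 2)
        abort_oct("f_max_hz aliases at the frame rate", "octmoco_value")
      fr <- stats::runif(n, fmin, fmax)
      ph <- stats::runif(n, 0, 2 * pi)
      # flat component amplitudes over the tremor band: with the large
      # per-frame steps reported for hand-held samples, a redder
      # spectrum would imply centimeter-scale drift within one C-scan
      am <- stats::runif(n, 0.3, 1)
      raw <- function(t) colSums(am * sin(outer(2 * pi * fr, t) + ph))
      base <- raw(0)                            # displacement from start pose
      tr <- raw(times) - base
      target <- ax$step_um %||% 0
      sc <- 1
      if (target > 0 && frames > 1L) {
        realized <- mean(abs(diff(tr)))
        if (realized > 0) sc <- target / realized
      }
      fun <- function(t) sc * (raw(t) - base)
      list(samples = sc * tr, fun = fun)
    }
  }
  axes <- if (kind == "freehand") {
    with_seed(seed, list(one_axis(params$axial), one_axis(params$lateral)))
  } else {
    list(one_axis(params$axial), one_axis(params$lateral))
  }
  structure(list(times = times,
                 axial_um = axes[[1]]$samples, lateral_um = axes[[2]]$samples,
                 fun_axial_um = axes[[1]]$fun, fun_lateral_um = axes[[2]]$fun,
                 kind = kind, seed = as.integer(seed)),
            class = "motion_trace")
}

#' Render one synthetic B-scan
#'
#' Draws a bright band of `band_thickness_px` centered on the (shifted)
#' true surface, axially blurred by `psf_sigma_px` (boxcar-times-
#' Gaussian profile, peak at the surface), multiplies the signal by
#' unit-mean exponential speckle, adds the background level, and
#' optionally overlays full-depth saturation stripes.  Deterministic
#' for a given seed.
#'
#' @param surface `phantom_surface`.
#' @param slice list: `axis = "fast"` with `at` = slow index y, or
#'   `axis = "slow"` with `at` = fast column x.
#' @param offsets numeric `(axial_px, lateral_px)` applied to the
#'   sample: the surface appears `axial_px` deeper, shifted `lateral_px`
#'   toward +x.  `axial_px` may also be a per-column vector (used to
#'   emulate motion during the frame's own acquisition), given as
#'   `list(axial_px = vector, lateral_px = scalar)`.
#' @param noise `noise_config`.
#' @param seed RNG seed; NULL draws from the current stream.
#' @return [bscan()].
#' @export
render_bscan <- function(surface, slice, offsets = c(0, 0),
                         noise = noise_config(), seed = NULL) {
  p <- surface$protocol
  ax_off <- if (is.list(offsets)) offsets$axial_px else offsets[1]
  lat_off <- if (is.list(offsets)) offsets$lateral_px %||% 0 else offsets[2]
  draw <- function() {
    if (slice$axis == "fast") {
      xs <- (seq_len(p$n_fast) - 1) - lat_off
      z0 <- surface_depth_px(surface, xs, slice$at) + ax_off
      ncol_out <- p$n_fast
    } else {
      ys <- seq_len(p$n_slow) - 1
      z0 <- surface_depth_px(surface, slice$at - lat_off, ys) + ax_off
      ncol_out <- p$n_slow
    }
    if (any(z0 < 1) || any(z0 > p$n_depth - 2))
      abort_oct("surface out of depth range", "octmoco_value")
    z <- seq_len(p$n_depth) - 1
    h <- noise$band_thickness_px / 2
    s <- noise$psf_sigma_px
    # boxcar (band) convolved with Gaussian PSF, peak-normalized
    prof <- stats::pnorm(outer(z, z0, `-`), -h, s) -
            stats::pnorm(outer(z, z0, `-`), h, s)
    prof <- prof / (stats::pnorm(h / s) - stats::pnorm(-h / s))
    img <- noise$band_amplitude * prof
    if (noise$speckle)
      img <- img * matrix(stats::rexp(length(img)), nrow(img), ncol(img))
    img <- img + noise$background_level
    if (noise$saturation_stripes > 0L) {
      cols <- sample.int(ncol_out, min(noise$saturation_stripes, ncol_out))
      img[, cols] <- img[, cols] + noise$saturation_intensity
    }
    img
  }
  px <- if (is.null(seed)) draw() else with_seed(seed, draw())
  role <- if (slice$axis == "fast") "fast" else "slow"
  bscan(px, role, index = slice$index %||% 0L, slow_position = slice$at)
}

#' Simulate a full motion-compensated OCT acquisition
#'
#' Frames `0 .. n_refs - 1` are slow-axis references at the protocol's
#' reference columns (rendered motion-free when `freeze_refs`, the
#' default and the method's working assumption); frames `n_refs ..`
#' are fast-axis B-scans at successive slow positions with the motion
#' trace's offsets converted to pixels.  Per-frame RNG seeds are
#' derived from `seed`, so the ground-truth motion-free volume is
#' rendered with identical speckle to the moving one.
#'
#' @param protocol `scan_protocol`.
#' @param surface `phantom_surface`.
#' @param motion `motion_trace` covering `n_refs + n_slow` frames.
#' @param noise `noise_config`.
#' @param seed master seed.
#' @param freeze_refs render references without motion (default TRUE).
#' @param render_static also render the motion-free twin volume
#'   (default TRUE; skip to halve simulation time when only the
#'   analytic ground truth is needed).
#' @param intra_frame when TRUE (default) and the motion trace carries
#'   its continuous evaluator, the axial offset of a fast-axis frame is
#'   sampled at every A-scan's own acquisition time within the 1/rate
#'   frame period, so motion during the B-scan tilts/curves the
#'   recorded surface — the effect the quadratic axial model exists to
#'   absorb.  FALSE applies one frame-constant offset.
#' @return list with `volume` (a `cscan_volume` with references) and
#'   `truth` (list: `z_true` matrix `n_slow x n_fast`, `axial_px`,
#'   `lateral_px` per C-scan frame, `static_volume` — the motion-free
#'   twin, and the `motion` trace).
#' @export
simulate_acquisition <- function(protocol, surface, motion,
                                 noise = noise_config(), seed = 1L,
                                 freeze_refs = TRUE, render_static = TRUE,
                                 intra_frame = TRUE) {
  p <- protocol
  need <- p$n_refs + p$n_slow
  if (length(motion$times) < need)
    abort_oct(sprintf("motion trace covers %d frames, need %d",
                      length(motion$times), need), "octmoco_value")
  ax_px <- motion$axial_um / p$axial_pitch_um
  lat_px <- motion$lateral_um / p$fast_pitch_um
  if (freeze_refs && p$n_refs + 1L <= length(lat_px)) {
    # frozen references define the lateral anchor pose: without this,
    # the trace drifting during the (frozen) reference interval would
    # insert a fictitious instantaneous lateral jump between the pose
    # the references saw and the first fast-axis frame.  Axial offsets
    # need no anchoring: they are observable absolutely via the
    # reference depths.
    lat_px <- lat_px - lat_px[p$n_refs + 1L]
  }
  refs <- vector("list", p$n_refs)
  for (i in seq_len(p$n_refs)) {
    off <- if (freeze_refs) c(0, 0) else c(ax_px[i], lat_px[i])
    refs[[i]] <- render_bscan(surface,
                              list(axis = "slow", at = p$ref_positions[i],
                                   index = i - 1L),
                              offsets = off, noise = noise,
                              seed = derive_seed(seed, i - 1L))
  }
  fidx <- p$n_refs + seq_len(p$n_slow)
  use_intra <- intra_frame && is.function(motion$fun_axial_um)
  frames <- static <- vector("list", p$n_slow)
  for (j in seq_len(p$n_slow)) {
    sl <- list(axis = "fast", at = j - 1L, index = fidx[j] - 1L)
    fseed <- derive_seed(seed, fidx[j] - 1L)
    off <- if (use_intra) {
      tcol <- motion$times[fidx[j]] +
        (seq_len(p$n_fast) - 0.5) / p$n_fast / p$bscan_rate_hz
      list(axial_px = motion$fun_axial_um(tcol) / p$axial_pitch_um,
           lateral_px = lat_px[fidx[j]])
    } else {
      c(ax_px[fidx[j]], lat_px[fidx[j]])
    }
    frames[[j]] <- render_bscan(surface, sl, offsets = off,
                                noise = noise, seed = fseed)
    if (render_static)
      static[[j]] <- render_bscan(surface, sl, offsets = c(0, 0),
                                  noise = noise, seed = fseed)
  }
  refset <- reference_set(refs, ref_x = p$ref_positions)
  z_true <- outer(seq_len(p$n_slow) - 1, seq_len(p$n_fast) - 1,
                  function(y, x) surface_depth_px(surface, x, y))
  list(volume = cscan_volume(p, frames, refset),
       truth = list(z_true = z_true,
                    axial_px = ax_px[fidx], lateral_px = lat_px[fidx],
                    static_volume = if (render_static)
                      cscan_volume(p, static, refset),
                    motion = motion))
}
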