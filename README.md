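# octmoco — motion compensation for volumetric corneal OCT

`octmoco` removes axial and lateral motion artifacts from volumetric
(C-scan) optical coherence tomography acquisitions of the cornea. It is
aimed at people building or evaluating OCT processing pipelines:
instead of registering images by cross-correlation, every fast-axis
B-scan is *segmented*, its anterior surface fitted with an order-4
polynomial

z(x) = p₅x⁴ + p₄x³ + p₃x² + p₂x + p₁,

and motion is deduced from the polynomials:

* **Lateral**: the integer shift minimizing the variance cost
  `Δlₜ = argmin var(|zₜ(x + Δl) − z₁(x)|)` against the first frame.
* **Axial**: before the C-scan, `t` reference B-scans are acquired
  along the slow axis (three by default, spacing ratio α = d/L); at
  each frame the offsets `a(xᵢ) = z(xᵢʳ) − zᵢʳ` to the reference
  surfaces are interpolated by an order `t − 1` polynomial and
  subtracted, `f(x) = z(x) − a(x)`.

The package also implements the Gaussian reference-placement theory —
per-reference accuracy `R(x; µ, σ) = exp(−(x − µ)²/2σ²)`, the
inverse-distance weighted combination `Y(x)`, and the placement error
`E(α, σ) = Σₓ[1 − Y(x)]`, whose minimum over α locates the optimal
reference spacing (α ≈ 0.34 for σ = 123, m = 1023) — plus a fully
seeded synthetic OCT acquisition simulator (speckled B-scans of corneal
phantoms under sinusoidal or band-limited free-hand motion, with ground
truth) so that the whole pipeline is testable by parameter recovery.
See the methods vignette (`vignettes/motion-compensation-methods.Rmd`)
for the model, assumptions, and design decisions.

## Worked example

Simulate a scaled acquisition (512 × 256 × 64 voxels, 3.6 µm/px axial,
100 Hz) of a quartic phantom under 700 µm / 1 Hz axial motion, then
compensate it:

```r
library(octmoco)

p      <- scaled_protocol(n_slow = 64L)
surf   <- phantom_surface(p, "quartic", apex_depth_px = 0.42 * p$n_depth,
                          ripple_amp_um = 4)
motion <- make_motion("sinusoid",
                      list(axial = list(amp_um = 700, freq_hz = 1)),
                      frames = p$n_refs + p$n_slow, rate = p$bscan_rate_hz)
sim    <- simulate_acquisition(p, surf, motion, noise_config(), seed = 42)

cfg <- compensate_config(preprocess = preprocess_config(border_crop = 12L))
res <- compensate_volume(sim$volume, cfg)
head(res$motion[, c("frame", "lateral_px", "a0", "a1", "a2")], 3)
#>   frame lateral_px       a0          a1           a2
#> 1     0          0 43.73217 -0.09087695 0.0004832912
#> 2     1          0 54.71522 -0.07901355 0.0004438539
#> 3     2          1 66.40837 -0.07460120 0.0004328565
```

`a0`–`a2` are the per-frame quadratic axial motion model in pixels
(frame 0 sits 43.7 px ≈ 157 µm deep into its 700 µm sinusoid);
`lateral_px` is the estimated lateral shift. Scoring against the
analytic motion-free surface:

```r
before <- volume_surfaces(sim$volume, cfg)
truth  <- sim$truth$z_true[, 13:(p$n_fast - 12)]
surface_error(before, truth, p$axial_pitch_um)
#> surface error over 64 frames x 232 columns:
#>   MAE  = 435.474 um
#>   RMSE = 480.264 um
surface_error(res$surfaces, truth, p$axial_pitch_um, observed = res$observed)
#> surface error over 64 frames x 232 columns:
#>   MAE  = 2.443 um
#>   RMSE = 3.238 um
```

The 700 µm motion corrugates the raw volume by ~435 µm on average;
compensation brings the mean absolute surface error down to 2.4 µm —
below one axial pixel (3.6 µm).

## Command line

```sh
exec/octmoco simulate   --config cfg.json --seed 1 --out out/sim
exec/octmoco compensate out/sim/volume.tiff --config cfg.json --out out/comp
exec/octmoco evaluate   a.tiff b.tiff --config cfg.json --out out/eval
exec/octmoco theory     --config cfg.json --out out/theory
```

Volumes are multi-page TIFFs (reference pages first) with a JSON
protocol sidecar; configurations are JSON with blocks `protocol`,
`preprocess`, `lateral`, `axial`, `synth`, `theory` (see
`inst/extdata/example_config.json`). Every run writes its resolved
config beside its outputs, so any artifact is reproducible from config
plus seed.

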