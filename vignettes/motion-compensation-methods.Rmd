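---
title: "Motion compensation for volumetric corneal OCT: model, simulator, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion compensation for volumetric corneal OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octmoco)
```

## The problem

A volumetric (C-scan) OCT acquisition of the cornea stacks hundreds of
fast-axis B-scans over a few seconds. Involuntary axial motion (pulse,
respiration) and lateral motion (tremor, drift) displace the sample
between B-scans, corrugating the reconstructed surface and ruining
quantitative measurements. `octmoco` implements a regression-based
compensation scheme: before the C-scan, a small number of *reference*
B-scans are acquired along the slow axis; every fast-axis B-scan is then
segmented, its anterior surface fitted with an order-4 polynomial, and
its motion deduced by comparing the fit against the first frame
(lateral) and against the reference surfaces (axial).

## The pipeline

Per B-scan `I0` (rows = depth `z`, columns = lateral `x`):

1. **Smoothing.** 10×10 sampled Gaussian, σ = 4 px, normalized,
   replicate padding (`gaussian_smooth`).
2. **Saturation removal.** `I = Ig − Ig * A`, `A` a 40-tap axial
   averaging filter (1/40 each). A saturated A-line is a near-constant
   bright stripe along depth, so it equals its own axial running mean
   and cancels (`remove_saturation`).
3. **Adaptive thresholding.** Foreground iff the rectified value
   strictly exceeds the local 64×64 mean times `1 + offset` (offset 0
   by default; `adaptive_threshold`). Rectification (`max(I, 0)`) is
   deliberate: the subtraction in step 2 leaves a negative halo around
   bright bands, and thresholding the signed image would promote the
   *empty* background beside that halo (value 0 against a slightly
   negative local mean) into a foreground sheet larger than the band
   itself, defeating the guarantee that the surface is the largest
   bright component. OCT intensities are non-negative; the rectified
   comparison restores that guarantee.
4. **Connected components.** The largest 8-connected foreground
   component is kept (`largest_component`; ties by brightest source
   pixel, then top-left-most pixel). A sanity check rejects
   "components" that are not band-like (more than 25 % of the image, or
   spanning fewer than half the columns) as *no surface found*.
5. **Initial surface + gradient refinement.** Per column, the
   shallowest component pixel; then the depth moves to the maximum of
   `F = (S*I0)² + (P*I0)²` within ±15 px, where `S`/`P` are Sobel and
   Prewitt kernels differentiating along depth (`gradient_image`,
   `refine_surface`). As printed, `F` omits the square root; a config
   switch (`gradient_sqrt`) exposes the magnitude variant — the
   refinement only ranks pixels within one A-line, so the choice does
   not change the result.
6. **Polynomial fit.** Least squares on the Vandermonde system
   `VP = Z` via the normal equations (`fit_surface`), order 4 by
   default. Columns are rescaled to [−1, 1] internally (a raw
   Vandermonde with x up to 1023 at order 4 is numerically hostile) and
   the coefficients mapped back, so `z(x) = p_{n+1}xⁿ + … + p₁` holds
   in pixel coordinates. Order 4 is the working default because lower
   orders cannot follow corneal topography while orders 5–6 chase
   speckle and local pathology (see `order_sweep`, which reproduces
   both regimes on phantoms).

**Lateral compensation** (`estimate_lateral_shift`): the integer shift
`Δl_t` minimizing `var(|z_t(x + Δl) − z_1(x)|)` over the overlap of the
two fitted domains, exhaustively over ±`search_px`. Variance makes the
cost blind to any constant axial offset, isolating lateral motion. Ties
prefer the smallest |Δl|, then the negative one; shifts with fewer than
10 overlapping columns are skipped. Positive `Δl` means the sample
moved toward +x between frame 1 and frame t; the image is translated by
−`Δl` with vacated columns zero-filled and *recorded* (see Evaluation).
Sub-pixel shifts are intentionally not estimated: columns are discrete
A-scans, and whole-column shifting is what the border crop is sized
for.

**Axial compensation** (`axial_offsets`, `fit_axial_motion`,
`compensate_axial`): at the frame's slow position `y_t`, the offsets
`a(x_i) = z_t(x_i^r) − z_i^r` against the (fitted) reference surfaces
are interpolated by the unique polynomial of order `n_refs − 1` — the
quadratic, for the default three planes — and subtracted:
`f(x) = z(x) − a(x)`. The image shifts by whole pixels
(`round(a(x))`), while the surface bookkeeping stays fractional; this
is how sub-pixel residual errors remain measurable on a 3.6 µm pixel
grid. Reference columns slightly outside a laterally-shifted frame's
fitted domain are evaluated by polynomial extrapolation, as the
published method implicitly does.

## Reference placement theory

The accuracy a reference plane at column µ lends to compensation at
column x is modelled as the peak-normalized Gaussian
`R(x; µ, σ) = exp(−(x − µ)²/2σ²)`. With three planes at
`µ = (1/2 − α, 1/2, 1/2 + α)·m` the combined accuracy is the
inverse-distance weighted mixture

`Y(x) = Σ wᵢ(x)Rᵢ(x) / Σ wᵢ(x)`, `wᵢ(x) = 1/(|x − µᵢ| + 1)`,

a convex combination (so `0 ≤ Y ≤ 1`, and `Y → R` as α → 0), and the
placement error is `E(α, σ) = Σₓ [1 − Y(x)]` over integer x in
[0, m]. `optimal_alpha` scans an α grid; `fit_sigma` fits σ to an
empirical error curve after min–max normalizing both (empirical curves
of this kind are reported normalized); `plane_positions` gives the
generalized even-distribution rule `(2i − 1)L/2t`.

Two numerical notes. First, the model as printed uses `µ₂ = n/2`
alongside "m = 1023"; the only reading that places the middle
reference mid-image is `µ₂ = m/2`, which is what `accuracy_model`
implements (same for the summation bound of E). Second, at σ = 123,
m = 1023 the functional is extremely flat: E changes by ~0.02 % between
α = 0.336 and α = 0.344. The fine-grid argmin is α = 0.342; on the
10/1024 grid used when this theory was originally matched to
experiment the argmin is 0.3418, i.e. "around 0.338" at that
granularity. Tests therefore compare the argmin with 0.338 at the
10/1024 grid step, not tighter — demanding more precision than the
functional's own flatness supports would be noise-chasing.
`optimal_alpha` breaks ties toward smaller α, where "tie" means equal
within 1e−8 per summed A-scan so that degenerate landscapes (σ ≫ m)
resolve deterministically.

## The synthetic acquisition simulator

The simulator exists so that every stage is checkable by parameter
recovery without OCT hardware. What it emulates, and what it does not:

* **Phantom surfaces** (`phantom_surface`): a gently aspheric quartic
  cap (defaults ≈ 137 µm sag over a 1 cm field — a shallow shell, so
  that surface plus the motion amplitudes under study fits the scaled
  depth window), an exact spherical cap, and a keratoconus-like local
  steepening bump. An optional few-µm sinusoidal irregularity
  (`ripple_amp_um`, default 0; the canned experiments use 4 µm at
  6.5 mm wavelength) makes the surface non-polynomial. This matters:
  on an *exactly* quartic phantom the order-4 fit is unbiased, every
  reference layout performs identically, and the reference-count and
  placement effects the theory describes vanish. Real corneal and
  shell surfaces are not polynomial at the micrometer scale; the
  ripple is the minimal stand-in for that.
* **Motion** (`make_motion`): sinusoids (multi-component if vectors are
  given) and band-limited "free-hand" traces — a sum of ≥ 8
  random-phase sinusoids with frequencies uniform on [0.5, 5] Hz and
  flat component amplitudes, rescaled so the mean |inter-frame step|
  matches the targets (14.18 µm axial, 165 µm lateral for the canned
  free-hand experiment). Flat amplitudes rather than 1/f: with 165 µm
  steps at 100 Hz, a red spectrum reaching ~0.15 Hz implies
  centimeter-scale drift within a single C-scan — the sample would
  leave the field — while the flat band keeps excursions at the
  few-hundred-µm scale. Traces are anchored to zero displacement at
  acquisition start.
* **Rendering** (`render_bscan`): a surface band of thickness 2 px,
  axially blurred with σ = 1.5 px (≈ the 4.5–6 µm axial resolution at
  3.6 µm/px), multiplied by unit-mean exponential speckle (the
  fully-developed speckle intensity model), plus optional full-depth
  saturation stripes. The background is dark (level 0) by default:
  with a nonzero noisy background, *any* local-mean threshold with
  zero offset marks ~half the background as foreground, so users
  adding background noise should raise `threshold_offset`. No
  wave-optics, refraction, or depth-dependent roll-off is modelled.
* **Protocol** (`simulate_acquisition`): `n_refs` slow-axis references
  first (motion-frozen by default — the method's stated working
  assumption; a flag renders them under motion to study that
  limitation), then the raster C-scan. When references are frozen the
  *lateral* trace is re-anchored at the first fast frame: otherwise
  the trace drifting through the frozen interval would insert a
  fictitious instantaneous jump between the pose the references
  record and the first frame. Axial needs no anchor (it is observable
  absolutely through the reference depths). With `intra_frame = TRUE`
  (default) the axial offset is sampled at each A-scan's own
  acquisition time within the 10 ms frame, so fast motion tilts and
  curves the recorded surface — precisely the within-B-scan effect
  the quadratic axial model exists to absorb, and the reason three
  references outperform two. Per-frame RNG substreams derived from
  the master seed make the whole volume bit-reproducible and give the
  motion-free twin volume identical speckle.

A green simulation test therefore establishes that the implementation
recovers the motion it injected under speckle, band-limited motion and
a realistic protocol — not that it would meet the same numbers on a
particular instrument, whose speckle statistics, surface reflectivity
and motion spectra differ.

## Evaluation

`surface_error` reports both the mean absolute per-A-scan surface
difference (MAE — the headline accuracy figure in this literature,
even when labelled "RMSE") and the true RMSE, in µm. Canned
experiments (`run_axial_experiment`, `run_freehand_experiment`,
`run_refcount_experiment`) score against the analytic motion-free
surface; scoring against a segmented static twin volume
(`compare = "static"`) is also provided and matches the
instrument-style protocol. Columns vacated by lateral compensation
carry no acquired A-scan — the surface there is polynomial
extrapolation — and are excluded via the `observed` mask. This
generalizes the fixed 50 px border crop, whose stated purpose is
removing exactly those empty A-scans; with free-hand excursions larger
than the (scaled) crop a global crop cannot do it alone.

The canned experiments use a proportionally scaled acquisition
(512 × 256 × 128 voxels instead of 1024 × 1024 × 512, same 3.6 µm axial
pitch, 100 Hz, crop 50 → 12 px) to keep runtimes in seconds. Two
consequences are worth knowing. Surface fits average 4× fewer columns,
so the error floor is roughly twice the full-size instrument's —
worst-seed errors at 1 Hz land near (sometimes slightly above) the
2.34 µm full-scale figure. And the free-hand lateral search range must
cover ±2 mm of excursion (the unbounded argmin of the cost is the
published formulation; `search_px = 160` at the scaled pitch).

The reference-count experiment uses a quasisinusoidal ~1 Hz motion
(500 µm fundamental + 90 µm tremor at 4.3 Hz): with a pure
frame-synchronous sinusoid, linear (2-reference) and quadratic
(3-reference) axial models differ only through a ~0.2 µm within-frame
quadratic residual, and the comparison degenerates into seed noise.
The tremor harmonic supplies within-B-scan curvature; the surface
ripple supplies the fit-residual field that more references track
better. Both mechanisms, not the bare sinusoid, are what make three
references measurably better than two.

## Degenerate inputs and numerical choices

* All convolutions use replicate padding; every filter equals a
  brute-force dense convolution oracle to 1e−10 in the tests.
* `fit_surface` requires ≥ order+1 distinct valid columns, else a rank
  error; invalid (no-foreground) columns are linearly interpolated and
  flagged, and participate in neither the fit nor the lateral cost.
* Frames whose processing fails (no surface, no admissible shift,
  motion exceeding the imaging depth) are passed through uncompensated
  and counted in the report rather than aborting the volume.
* TIFF I/O is a minimal self-contained baseline codec (uncompressed
  grayscale, 8/16-bit unsigned or 32-bit float, one strip per page);
  it reads big-endian and multi-strip uncompressed files but writes
  little-endian single-strip only, and is cross-checked against an
  independent TIFF implementation in the test suite. Sidecars,
  reports and run configurations are JSON.
* `motion_spectrum` Hann-windows before the DFT: over a ~1 s trace a
  rectangular window would leak band-limited energy far above the
  band and make band-limitation untestable at the band edge.

## Known limitations

* Lateral motion along the slow axis (y) is neither simulated nor
  compensable by the published scheme; a y-shift masquerades as a
  surface change.
* Alignment to frame 1 assumes frame 1 is representative; its own
  pose becomes the lateral origin of the compensated volume.
* The accuracy theory's σ is a free parameter here: fitting σ to real
  instrument data requires that instrument's error curve, which is not
  reproducible from synthetic data (self-consistency recovery of σ is
  tested instead).
* Only the anterior surface is segmented; posterior/multi-layer
  segmentation is out of scope.
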