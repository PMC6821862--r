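---
title: "optomo: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{optomo: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optomo)
```

## The imaging model

Optical projection tomography rotates a transparent sample through a full
revolution in front of a telecentric lens. Telecentricity means constant
magnification across depth, so each projection is a **parallel-beam** line
integral of the object — the Radon transform — and the efficient filtered
back-projection (FBP) inversion applies. `optomo` assumes this model
throughout: no fan- or cone-beam weighting, no refraction, no PSF model
(deconvolution-based forward models are out of scope).

Two modalities share the machinery. In transmission (tOPT) the camera
measures `I = I0 · exp(-A)` where `A` is the line-integrated attenuation;
FBP needs `A`, so raw projections are converted by
`A = -ln(max(I, floor) / max(I0, floor))` against an averaged bright-field
image `I0`. The floor (default 1 count) prevents `-ln(0)`; negative `A`
(noise pushing `I > I0`) is clamped to zero by default because unphysical
negatives streak under the ramp filter — a flag keeps signed values for
diagnostic use. In emission (eOPT) the projections are already linear in
fluorophore density and only dark/flat-field correction applies (the flat is
normalized to unit mean so the global intensity scale survives).

## Coordinate and sign conventions

* Indices are 0-based in user-facing coordinates; pixel centers sit at
  integers; the center of an `n`-pixel axis is `(n-1)/2` (a float, symmetric
  for even and odd `n` — required for sub-pixel axis offsets).
* The rotation axis is nominally vertical (along the image row index), so
  one sinogram is extracted per image row.
* A point at slice offset `(dy, dx)` from the axis projects to detector
  coordinate `s = dx·cos θ − dy·sin θ`. The simulator and the
  back-projector share this single constant, and a bead round-trip test
  (reconstructed bead centroid vs ground-truth 3-D position) pins it.
* Bead motion is parameterized as `v(θ) = A·cos(θ + φ) + c` with `φ` in
  degrees normalized to `[-180, 180)` (ties resolve to −180).

## Geometric calibration from one bead

The paper-style calibration uses a single fiducial bead. Writing the bead's
axis-frame position as `(dz, dy, dx)` and propagating it through explicit
rotation matrices gives the detector trace

* horizontal: `x(θ) = c + A cos(θ + φ)`, with `A cos φ = dx`,
  `A sin φ = dy`;
* vertical, in-plane axis tilt `α`: a component **in phase** with `x(θ)`,
  amplitude `A sin α` (ratio `tan α` after accounting for the `cos α`
  foreshortening of `A`);
* vertical, out-of-plane lean `β`: a **quadrature** component
  `A sin β · sin(θ + φ)`.

`estimate_geometry()` therefore fits the horizontal sinusoid (closed-form
linear least squares on `a cos θ + b sin θ + c` — exact on noiseless data at
≥ 4 angles spanning > 180°), then regresses the vertical track on
`cos(θ + φx)` and `sin(θ + φx)`: `tilt_inplane = atan(P / A_x)` from the
in-phase coefficient `P`, `tilt_outplane = asin(Q / A_x)` from the
quadrature coefficient `Q`. The property suite verifies both signatures
against an independent oracle that rotates explicit 3-D point coordinates,
never touching the image-warp code path.

Out-of-plane tilt mixes detector **rows**, which a per-slice 2-D FBP cannot
undo, so it is diagnostic-only; correction uses offset + in-plane tilt. With
horizontal amplitude below 1 px the tilt ratios are numerically meaningless
and are returned as `NA` (the offset, which needs only the trace mean, is
still returned).

Jitter correction: the residuals of the horizontal fit are, per angle,
exactly the lateral displacement of that projection; `dynamic_offset()`
returns their negation and `create_sinograms()` applies them as additive
sub-pixel column shifts (linear interpolation, zero fill), together with
`-axis_offset` and the `-tilt` rotation. Note the sign: corrections are the
*shifts to apply*, already negated — applying them must cancel injected
jitter, and the acceptance suite checks exactly that (σ = 2 px recovered to
< 0.5 px RMSE; ≥ 50 % reconstruction-RMSE reduction).

## Filtered back-projection

Each sinogram row of width `W` is zero-padded to the next power of two
≥ 2`W` (padding factor 2 by default; larger factors push the circular
wrap-around of the ramp kernel further out), multiplied in the frequency
domain by

* ramp: `H(f) = |f|` up to Nyquist `f_N = 1/(2·pitch)`;
* Shepp–Logan: `|f| · sinc(f / 2f_N)`;
* Hamming: `|f| · (0.54 + 0.46 cos(π f / f_N))`;
* none: all-pass (plain back-projection, for inspection),

and back-projected with linear interpolation. The DC sample of the ramp is
not zero but the sum of the discrete banded Ram-Lak spatial kernel
(`h(0) = 1/4`, `h(odd m) = −1/(π² m²)`, scaled by the pitch); a zero DC
would bias the reconstruction mean low.

**Normalization.** With `H = |f|`, the inversion constant is
`π / n_angles` — for a half revolution it is the angular step `Δθ = π/N`,
and for a full revolution the double coverage of every direction halves
`Δθ = 2π/N` to the same value. (Toolboxes that scale by `π/(2N)` pair it
with a `2|f|` filter; the two conventions are identical end-to-end.) The
centered-disk example pins the amplitude: a unit disk reconstructs with an
interior plateau in `[0.9, 1.1]` and background in `[-0.05, 0.05]`. Pixels
outside the inscribed circle, where a `W`-wide detector never provides
complete data, are set to zero.

A full revolution is reconstructed from all `N` angles rather than averaging
opposing pairs: the redundancy averages measurement noise inside the
accumulation, which is the reason full-revolution scans give higher image
quality in practice.

Slices are processed independently with no RNG and no shared state, so the
`workers` argument (forked workers via `parallel::mclapply`) is contractually
result-invariant; a test compares 1 vs 4 workers at 1e-10.

## The simulator as the testing instrument

`forward_project()` rotates the phantom volume slice-by-slice by `-θ`
(bilinear interpolation, zero padding), optionally leans it about the
detector x-axis (out-of-plane tilt, a second separable 2-D warp), integrates
along the optical axis, rotates the projection in-plane (in-plane tilt),
shifts it by the axis offset plus the per-angle jitter draw, multiplies a
smooth illumination field, and applies noise. Defaults mirror the stated
acquisition world:

| parameter | default | reason |
|---|---|---|
| projections | 512 over 360° | the full-revolution acquisition count used for high-fidelity scans |
| minimum step | 360/1024 = 0.35° | 1024-step stepper-motor revolution |
| jitter σ | 2 px | test-convenience choice; the motors' jitter amplitude in px is not quantified anywhere, flagged as such |
| illumination | polynomial bump, center/edge ratio 1.5 | emulates uneven collimation in raw tOPT projections |
| noise | Gaussian in counts, or Poisson at a set mean photon count | camera read noise / shot noise |
| fiducial | Gaussian-profile sphere, radius 2 px | the glass bead tracked for calibration |

Two rendering/testing choices deserve emphasis:

* **Phantoms are rasterized with 4×4 area sampling** (anti-aliased edges).
  A binary-membership rasterization puts frequency content above Nyquist
  into the "ground truth" that no band-limited reconstruction can
  reproduce, deflating oracle agreement for reasons unrelated to the
  reconstruction. With area sampling the Shepp–Logan forward/FBP round trip
  reaches Pearson ≈ 0.984, RMSE ≈ 0.041 on the unit scale, matching what
  reference implementations achieve with anti-aliased phantoms.
* **The angle-count monotonicity property is evaluated with fixed-seed
  measurement noise** (Gaussian, σ = 0.5 counts ≈ 1.7 % of the peak line
  integral). Noiselessly, reconstruction error saturates at the
  interpolation floor near 256 angles on a 96 px detector and the 256 vs
  512 comparison becomes a coin flip at the 1e-5 level; the streak-artifact
  phenomenon the property encodes is about measured data, and with noise
  the RMSE sequence over {64, 128, 256, 512} angles is strictly decreasing
  and reproducible.

What a green simulation test does **not** establish: performance on real
cleared-organ data (scatter, refraction through agarose and clearing medium,
depth-dependent blur from the lens PSF, detector nonlinearity are all
unmodeled), the absolute resolution figures of any physical instrument, or
the behavior of the tracker on low-contrast beads over structured
backgrounds. The headline biological numbers of the instrument this package
models (≈ 50 µm organ-scale resolution, labelling-strategy SNR ratios)
depend on real datasets and are deliberately not asserted anywhere; the SNR
comparison in the test suite is a constructed scenario (2.5× label density
recovers a 2.5× SNR ratio) that validates the statistic, not the biology.

## Resolution metrics

FRC follows the split-projection protocol: the stack is divided into
even- and odd-indexed angle subsets — each spanning the full range at twice
the step — both halves are reconstructed, and the ring-wise correlation of
their 2-D Fourier transforms is averaged over sampled slices before
thresholding. The threshold is the fixed-value 1/7 criterion (the
source instrument's threshold choice is not documented; the value is
recorded in every `frc_result` so half-bit or other criteria can be added
without breaking outputs). Rings are one frequency sample wide on the
per-slice 2-D transform (not 3-D shells), matching the slice-wise
protocol. Images are mean-subtracted and cosine-tapered over a 10 % margin
before transforming — both steps are flags — to suppress spectral leakage
from non-periodic boundaries; the taper is why a "flat" FRC ring can be
marginally below 1 even for identical inputs away from the tested
tolerance. A curve that never crosses the threshold reports "not reached"
rather than clamping to Nyquist.

`profile_fwhm()` samples a line with bilinear interpolation, subtracts the
baseline estimated from the profile's end thirds, and interpolates the
half-maximum crossings around the peak. `roi_stats()` defines
`snr = (mean_signal − mean_background)/sd_background` and
`br = mean_background/mean_signal`; these formulas are package conventions
(the instrument's exact definitions live in unavailable supplementary
material) and are validated only on constructed data.

## Degenerate inputs and tie-breaks

* `fit_sinusoid()` refuses < 4 usable samples or an angular span ≤ 180°.
* Tracking failures are flagged, never interpolated; > 20 % failures abort
  with per-angle diagnostics. Failed angles contribute correction 0.
* Beads on the axis (amplitude < 1 px) yield `NA` tilts, valid offset.
* `atan2` phase ties at ±180° resolve to −180°.
* An all-zero sinogram reconstructs to an all-zero slice (linearity).
* Non-finite values are rejected at container boundaries: attenuation
  stacks must be finite, uint16-scaled TIFF export refuses NaN/Inf.

## I/O

Multi-page little-endian grayscale TIFF with a `key: value` sidecar manifest
(geometry, stage, scaling) — TIFF tags vary too much across dialects to
carry metadata portably, and no R TIFF package is available in the target
environment, so the package ships a minimal baseline codec: uncompressed,
8/16-bit unsigned or 32-bit float, single- or multi-strip reading. `float32`
round trips bit-exactly; `uint16-scaled` records `scale_min`/`scale_max` in
the manifest and is exact to `(max−min)/65535`. Lexicographic file order
defines angular order for single-page directories; a manifest overrides.

## Known limitations

* Pure-R warps: forward projection of large volumes is O(angles × voxels)
  with bilinear gathers; fine at calibration/test scales, slow for
  full-frame organ stacks (the acceleration contract is worker-count
  invariance, not a GPU port).
* Out-of-plane tilt is detected but not corrected (requires row remixing,
  i.e., a 3-D resampling step outside per-slice FBP).
* Single-bead calibration: no multi-bead bundle adjustment, no marker-free
  sinogram-consistency center finding.
* The TIFF codec reads only the baseline dialect it writes (plus plain
  uncompressed grayscale from other writers); no OME-TIFF, no compression,
  no streaming of larger-than-memory stacks.
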