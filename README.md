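# optomo

Reconstruction and calibration toolkit for **optical projection tomography
(OPT)** — the mesoscale cousin of X-ray CT that images transparent,
millimeter-to-centimeter biological samples (cleared organs, embryos,
organoids) by rotating them through a full revolution in front of a
telecentric lens and collecting one 2-D projection per angle.

`optomo` implements the full post-acquisition chain for parallel-beam OPT in
R, plus a forward simulator so every algorithm can be verified by parameter
recovery without a microscope:

1. **Projection correction** — transmission (tOPT) projections are divided by
   an average bright-field image and log-transformed per the Beer–Lambert law
   `I = I0 e^{-A}`, yielding line-integrated attenuation `A`; emission (eOPT)
   projections get dark/flat-field correction.
2. **Geometric calibration** — a small glass fiducial bead embedded next to
   the sample is tracked across the projections. An ideal bead at radius `r`
   from the rotation axis traces `x(θ) = c + A cos(θ + φ)` on the detector;
   the closed-form least-squares fit of that sinusoid gives the rotation-axis
   **offset** (`c` minus the detector center) and, from the bead's vertical
   motion, the axis **tilt**: the in-phase vertical component has amplitude
   ratio `tan α` (in-plane tilt, correctable), the quadrature component
   `sin β` (out-of-plane lean, reported as a diagnostic).
3. **Jitter correction** — low-cost stepper motors displace the sample
   laterally by a random amount per angle. The per-angle residuals of the
   sinusoid fit *are* the jitter; their negation is applied as sub-pixel
   column shifts to produce a smooth sinogram ("dynamic offset correction").
4. **Filtered back-projection** — per-slice FBP with selectable frequency
   filters (ramp `|f|`, Hamming- and Shepp–Logan-windowed ramp, or none),
   power-of-two zero padding, linear-interpolation back-projection, and the
   `π/N` accumulation constant; slices are independent, so reconstruction
   parallelizes with bit-identical results.
5. **Quality metrics** — Fourier ring correlation (FRC) resolution from
   split-projection half-scans (even vs odd angles, threshold 1/7), profile
   FWHM, and region SNR / brightness-ratio statistics.

Stacks, sinograms and volumes travel as multi-page grayscale TIFF with a
plain-text `key: value` sidecar manifest; a minimal baseline TIFF codec is
built in (no external imaging dependency).

## Worked example

Simulate a misaligned, jittery scan of a disks-plus-fiducial phantom, then
calibrate, correct, reconstruct, and estimate resolution:

```r
library(optomo)

geom <- acquisition_geometry(256, pixel_size_um = 12.9)
#> <acquisition_geometry> 256 projections over 360 deg (step 1.406 deg), tOPT, 12.9 um/px

phantom <- make_phantom("disks", c(20, 96, 96))
phantom$voxels[10:20, , ] <- 0                      # keep the upper rows clear
bead <- make_phantom("bead", c(20, 96, 96),         # fiducial above the sample
                     center = c(15, 47.5 + 8, 47.5 + 20), radius = 2, value = 2)
phantom$voxels <- phantom$voxels + bead$voxels

scan <- forward_project(phantom, geom,
                        artifact_spec(axis_offset_px = 5.25,
                                      jitter_sigma_px = 2, jitter_seed = 7))

track <- track_fiducial(scan$stack, seed_roi = c(11, 0, 9, 96))
model <- estimate_geometry(track, detector_center_col(96))
#> <geometry_model> offset=5.381 px, tilt in-plane=-4.63e-15 deg, out-of-plane=1.79e-14 deg (estimated)

corr <- dynamic_offset(track)
sqrt(mean((as.numeric(corr) + scan$jitter_shifts)^2))
#> jitter recovery RMSE: 0.188 px

vol <- reconstruct_volume(scan$stack, model, corr, filter_spec("ramp"), rows = 2:7)
#> <opt_volume> 6 x 96 x 96 voxels, 12.9 um/voxel
```

The estimated axis offset (5.38 px) recovers the injected 5.25 px to within
the bead-localization error, the per-angle jitter is cancelled to 0.19 px
RMSE, and the corrected reconstruction reaches RMSE 0.034 against the ground
truth slice versus 0.182 uncorrected. The split-half FRC of the corrected
stack reports resolution at the sampling floor:

```r
frc_resolution_from_halves(scan$stack, model, corr, rows_sample = 4)
#> <frc_result> 49 rings, threshold 0.143, resolution 2.60 px
```

## Command line

Every stage is also a subcommand of the installed launcher
(`system.file("cli", "optomo", package = "optomo")`):

```sh
optomo simulate --phantom disks --n-proj 512 --offset 5.25 --jitter 2 --seed 7 --out scan/
optomo correct --mode beer-lambert --bright bright.tif scan/projections.tif corrected.tif
optomo track corrected.tif track.csv
optomo calibrate track.csv --width 1040 --out geometry.manifest
optomo dejitter track.csv --out corrections.csv
optomo reconstruct corrected.tif --geometry geometry.manifest \
       --jitter corrections.csv --filter ramp --rows 0:1040 --out volume.tif
optomo frc corrected.tif --filter ramp --rows 100:110 --pixel-size 12.9 --out frc.csv
optomo run --manifest config.manifest      # the whole pipeline, one seed
```

All subcommands exit nonzero on error.

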