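# roctscan

Robotic large-area optical coherence tomography (OCT) scanning, simulated
end to end: raster scanline planning, image-feedback probe-altitude
control, pose-based 3D reconstruction of tracked B-scans, and large-area
2D parameter maps of tissue surface, optical attenuation and tubule-lumen
calibre. The package targets workflows such as ex-vivo kidney assessment
before transplantation, where a robot-mounted OCT probe must sweep a
sample far larger than a single B-scan field of view while keeping the
tissue surface at a constant depth in the image.

Everything runs against a built-in virtual scanner: synthetic scenes
(letter-extrusion accuracy phantoms and kidney-like tissue with capsule,
vessels and tubule lumens) are rendered into physically plausible B-scans,
so no hardware or external data is required. User-supplied scans — a
multi-page TIFF stack, a pose-log CSV and a JSON pixel-geometry sidecar —
run through the same analysis path.

## The model

**Scan planning.** Scanlines run along the base-frame x axis, spaced along
y so adjacent lateral fields of view overlap. With lateral FOV `W_OCT`,
coverage width `W` and overlap `W_ol`, the number of lines is

    n = ceil( W / (W_OCT − W_ol) ),   valid when  W_OCT > 2·W_ol > 0.

**Altitude control.** Each B-scan is reduced to the normalized surface
depth (NSD) of the highest detected tissue point (`h_tis` of `H_OCT` axial
pixels):

    µ = 1 − h_tis / H_OCT,

regulated to the setpoint µ̃ = 0.75 by a low-pass-filtered proportional
velocity law

    v_z[t] = w_s · K_p · (µ̃ − µ) + (1 − w_s) · v_z[t−1],

with the commanded altitude clamped to a configured safety range.

**Reconstruction.** Every pixel of every tracked B-scan maps to the robot
base frame through the recorded probe pose (a homogeneous transform per
frame) and is voxelized into a tissue volume `V_tis`; overlapping
contributions are averaged.

**Parameter maps.** Three top-view maps are extracted per scanline and
stitched (overlaps averaged):

- **DEPM** — surface altitude per (x, y) column of `V_tis`;
- **ATCM** — per-A-scan extinction coefficient µ_t from a least-squares
  fit of the single-scattering decay `I(z) ∝ exp(−2·µ_t·z)` in a ~1 mm
  window below the surface;
- **DIAM** — mean tubule-lumen diameter: slice-wise segmentation of dark
  lumens (pluggable; a classical attenuation-normalized thresholder is
  the default), area closing/opening, skeleton ("centerline") plus
  Euclidean distance transform per component, block-averaged on a k×k
  grid (k = 10) and bicubically upsampled.

**Speed sweep.** Faster scanning at a fixed 20 fps B-scan rate is
emulated by keeping every `round(v/v_ref)`-th elevational line; map
degradation is scored with a windowed structural-similarity index (SSIM).

## Worked example

```r
library(roctscan)

geom  <- pixel_geometry(res_lateral = 2.73e-3, res_axial = 2.68e-3,
                        n_lateral = 256, n_axial = 300)
scene <- make_kidney_scene(extent = c(0, 2, 0, 1.2), relief_amplitude = 0.1,
                           correlation_length = 1.5, parenchyma_mu = 1.5,
                           capsule_mu = 3, capsule_thickness = 0.05,
                           lumen_density = 10, lumen_diameter_mean = 40,
                           seed = 42)
plan  <- plan_scanlines(x_st = 0.2, y_st = 0.35, z_st = 2, L = 1.5, W = 0.9,
                        W_ol = 0.25, geom = geom, v_x = 0.6, frame_rate = 20)
plan
#> <scan_plan> 3 line(s) of 1.5 mm at 0.6 mm/s, lateral step 0.449 mm (overlap 0.25 mm)

state <- controller_state(z_min = -1, z_max = 3)
scan  <- execute_scanline(scene, plan, 1, geom, state, speckle_sd = 0.2,
                          seed = 1)
sprintf("NSD held at %.3f +/- %.4f over %d frames",
        mean(scan$telemetry$mu), sd(scan$telemetry$mu), nrow(scan$telemetry))
#> "NSD held at 0.752 +/- 0.0163 over 50 frames"

vol  <- voxelize_scan(scan)
vol
#> <tissue_volume> 50 x 256 x 323 voxels of (0.03, 0.00273, 0.00268) mm, 92.9% filled

amap <- atcm(scan)
sprintf("ATCM: mean mu_t = %.2f mm^-1", mean(amap$values[amap$valid]))
#> "ATCM: mean mu_t = 1.32 mm^-1"

msk  <- clean_mask(segment_volume(vol))
recs <- measure_diameters(msk, pitch_mm = vol$voxel_size[2],
                          origin = vol$origin, voxel_size = vol$voxel_size)
sprintf("DIAM: %d lumen cross-sections, mean %.1f um (population truth %.1f um)",
        nrow(recs), mean(recs$diameter_um),
        mean(scene$metadata$lumen_diameters_um))
#> "DIAM: 286 lumen cross-sections, mean 38.2 um (population truth 39.5 um)"
```

The controller holds the surface at 0.752 NSD against 0.1 mm relief and
20% speckle. The mean fitted attenuation (1.32 mm⁻¹) sits below the
parenchyma value because the fit window also sees the brighter capsule
stratum and the dark lumens — exactly the contrast the ATCM visualizes.
The recovered lumen diameters track the programmed 40 µm population
within a few percent.

A file-based pipeline (`run_pipeline()`, or the `inst/cli/roct` script
with subcommands `make-scene`, `plan`, `scan`, `reconstruct`, `map`,
`stitch`, `sweep`, `evaluate`, `all`) produces the same artifacts on disk
with a checksummed run manifest; reruns from the same config and seed are
byte-identical.

## Method details

See the methods vignette (`vignettes/roctscan-methods.Rmd`) for the image
formation model, controller tuning, numerical conventions and known
limitations.
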