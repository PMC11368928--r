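---
title: "Methods: simulating and analysing robotic large-area OCT scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing robotic large-area OCT scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its models and the choices
behind them: the image-formation model of the virtual scanner, the
closed-loop altitude controller and its tuning, the reconstruction and
parameter-map conventions, what the synthetic scenes do and do not
emulate, and the known limitations.

## Coordinate frames and units

All computation is in millimetres and seconds. The probe frame originates
at the top centre of the B-scan: x points along the elevational (scan)
direction, y along the B-scan lateral axis, z along the axial axis into
the tissue. During scanning the probe looks straight down, so its
orientation relative to the base frame is the fixed rotation
`diag(1, -1, -1)`: probe z maps to "down" and probe y to "-y" of the
base. Pixel indices are 0-based and address pixel centres, which puts the
(0, (n_lateral-1)/2) pixel exactly at the frame origin. A pixel (row,
col) maps to probe coordinates
`(0, (col - (n_lateral-1)/2)·res_lateral, row·res_axial)` and from there
to the base frame through the recorded pose. The default pixel geometry —
2.73 µm lateral, 2.68 µm axial, 1800 × 700 pixels at 20 fps — mirrors a
spectral-domain system configuration for kidney work; every test and
study states its own (usually smaller) raster.

The lateral field of view is always derived from the pixel geometry
(`n_lateral · res_lateral`), with an explicit override available in
`plan_scanlines()`. Published system descriptions sometimes quote
scanline counts and overlaps that imply a wider FOV than the pixel
arithmetic gives; the package makes no attempt to reconcile such numbers
and treats the geometry as authoritative.

## Image formation in the virtual scanner

`render_bscan()` implements single-scattering image formation. For each
lateral column the ray is sampled at the axial pitch; a pixel a depth `d`
below the surface receives

    I(d) = I0 · b(d) · exp(-2 · M(d)),    M(d) = ∫₀ᵈ µ_t(s) ds,

where `M` accumulates the local extinction along the A-scan — the layered
background (a capsule stratum of configurable thickness over parenchyma
whose µ_t may vary laterally) plus analytic path corrections for every
ellipsoidal inclusion the ray crosses — and `b` is the relative
backscatter, 1 in tissue and ≪ 1 inside tubule lumens, which is what
renders them dark. The accumulated integral is evaluated in closed form
from the fractional surface row, so with zero speckle the log-intensity
of a uniform column is exactly linear in depth with slope −2µ_t (the
renderer-vs-fit tests assert R² = 1 to 1e-10). The surface itself is a
one-pixel specular line (intensity 0.8 by default, inside the detection
band; saturated-reflection handling is exercised with explicit fixtures),
pixels above it carry a low background level, and intensities are clipped
to [0, 1] — detector units are arbitrary, so normalized intensity is used
throughout.

Speckle is multiplicative log-normal noise with mean 1
(`exp(N(-sd²/2, sd))`) applied to the whole image. No published noise
statistics were available for the emulated system, so the speckle level
is a free parameter; recovery tolerances in the tests are stated at
`speckle_sd = 0.2`, a level at which the speckle standard deviation is
20% of the local mean — strong enough that single-pixel statistics are
unreliable and averaging is required, which is the regime real OCT
operates in. There is no confocal/roll-off factor, no refraction, no
shadowing and no multiple scattering: anything richer than the
single-scattering model would be unverifiable against the quantities the
package recovers.

## Synthetic scenes

Two generators define the study conditions.

`make_letter_phantom()` builds the localization-accuracy phantom: a flat
base with letter-shaped extrusions assembled from axis-aligned
rectangular strokes (overlaps take the maximum height), uniform
attenuation, no lumens. Ground truth per glyph — the bounding extent
along the scan and lateral axes and the extrusion height — is stored in
the scene metadata and consumed by `evaluate_depm_accuracy()`.

`make_kidney_scene()` emulates the renal anatomy relevant to large-area
OCT: a band-limited random surface (white noise on a coarse lattice,
Gaussian-smoothed to the stated correlation length, scaled to the relief
amplitude), a thin higher-attenuation capsule over parenchyma, optional
superficial low-attenuation vessel-like tubes, and a population of dark
tubule lumens. Lumens are strongly elongated horizontal ellipsoids at
random azimuth, long enough to span past the footprint. This choice is
deliberate: proximal-tubule lumens are convoluted tubes, and a compact
ellipsoid population would not measure its nominal diameter — random
planar cuts through spheres average π/4 of the true bore, a 21% bias that
is a property of the phantom, not the measurement. Cross-sections of
long tubes, by contrast, carry the sampled diameter essentially
everywhere, and the centerline measurement (below) is designed to recover
the bore of obliquely cut tubes. The vertical semi-axis is used for the
strictly-below-surface validity check, since the long axis is horizontal.

What the scenes do **not** emulate: real speckle statistics and axial
point-spread blur, surface specular lobes, refraction at the air–tissue
interface, heterogeneous backscatter textures, and organ-scale anatomy
(calyces, vasculature trees). Passing recovery tests therefore
demonstrates that the analysis chain is correct and robust at realistic
noise levels — not that it is validated on real tissue.

## Scan planning and the landing motion

`plan_scanlines()` enforces `W_OCT > 2·W_ol > 0` and computes
`n = ceil(W / (W_OCT - W_ol))` lines; line i starts at
`y_st + (i-1)(W_OCT - W_ol)`. The lateral footprint of a line is centred
on its y coordinate, consistent with the top-centre frame origin. The
entry altitude `z_st` must put the sample out of the axial FOV; the
landing motion then descends in fixed steps (`descent_speed · dt`,
0.1 mm by default), rendering and detecting at each step, and locks on at
the first step where the NSD reaches its setpoint. The lock-on NSD
therefore overshoots the setpoint by at most one step of altitude; the
closed loop removes that residual within its settling time.

## Surface detection and NSD regulation

`detect_surface()` is deliberately simple: per column, the surface is the
topmost pixel inside an intensity band `[lower, upper]` that starts a run
of at least `m_persist` in-band pixels. The upper bound rejects saturated
specular reflections above the true surface; the persistence rejects
isolated noise. Defaults (0.15, 0.85 of full scale, m_persist = 3) are
config values — no published thresholds exist for the emulated system.
`h_tis` is the minimum valid surface row (the single highest point, as
defined); a percentile variant can be had by post-processing
`surface_rows`, but the highest point is what the regulation law is
specified against.

The controller output is
`v_z[t] = w_s·K_p·(µ̃ − µ) + (1 − w_s)·v_z[t−1]`, positive output
commanding descent, integrated explicitly at the 20 fps frame period —
the image rate is the testable contract even though a physical arm would
run a faster inner loop. Frames that lose the surface hold the last valid
µ rather than zeroing the command, so the filtered velocity decays
smoothly across detection dropouts. The commanded altitude is clamped to
`[z_min, z_max]` at every step, and a property test drives the loop with
adversarial NSD sequences to confirm the clamp.

**Tuning.** The defaults K_p = 6 mm/s per unit NSD and w_s = 0.4 come
from a quantized flat-scene step-response study
(`inst/scripts/tune_controller.R`): with the default axial FOV of
1.876 mm, the discrete loop's pole is `1 − K_p/(f·H_OCT)`, and K_p = 6 is
the smallest gain in the sweep whose 0.05-NSD step settles to within one
axial pixel inside 1 s at 20 fps with zero overshoot (18 frames); softer
gains in the 2 mm/s range settle in 3–4 s, which a 95%-in-band
requirement over a long scanline cannot absorb. On a ramp of slope `s`
the proportional loop leaves the classical steady-state lag
`s·v_x / K_p` in NSD units, which the simulation reproduces.

## Reconstruction

`pixels_to_base()` composes the pixel-to-probe map with each frame's pose;
`voxelize()` bins points with the half-open floor convention (a point on
a boundary joins the higher-index voxel) and averages contributing
intensities, retaining counts so streams pool exactly. The default voxel
size is `(v_x/frame_rate, res_lateral, res_axial)` — the elevational
pitch follows from kinematics, so each frame fills one voxel slab and
adjacent-scanline overlaps are the only multi-contributor voxels; they
are averaged, matching the map-stitching rule. Grids are pre-sized from
the pose extremes and expand (never drop) on out-of-range points.
Unobserved voxels hold the declared fill 0, which downstream steps treat
as "no data".

## Parameter maps

**DEPM** applies the same band-plus-persistence rule as surface detection
down each (x, y) voxel column and reports the base-frame altitude of the
topmost in-band voxel — pose-independent, unlike a depth-below-probe
convention. `evaluate_depm_accuracy()` thresholds the map at half the
extrusion height inside a padded window around each glyph and compares
bounding extents per axis; extents are translation-invariant, so
positional offsets are deliberately not scored.

**ATCM** fits ln I against depth by least squares over a window
(default 1 mm) starting `offset_rows = 5` pixels below the detected
surface (skipping the specular line), excluding samples at or below an
intensity floor, and requires at least 10 usable samples; µ_t = −slope/2,
clamped at 0. A linear fit on log-intensity was chosen over a nonlinear
exponential fit because it is exact under the generative model, fast
enough to run per A-scan over a whole volume, and its failure mode
(an invalid fit) is explicit.

**DIAM** segments each elevational slice of the volume with a pluggable
segmenter. The classical default aligns columns by the detected surface
and flags pixels far darker (ratio below 0.5) than the expected intensity
at their depth. The expected depth profile is pooled over the whole
volume as a per-depth median (from a 256-bin histogram), not per slice: a
large tubule cut near-parallel to the B-scan plane can dominate one depth
of one slice and would otherwise masquerade as its own background.
Depths whose expected intensity falls below a floor (0.05) are considered
too attenuated to segment. Masks are cleaned by slice-wise area closing
then area opening (defaults A_c = A_o = 20 px; no published values
exist), implemented by component-area filtering of the background and
foreground respectively. Per component, the diameter is the mean over
skeleton pixels of twice the Euclidean distance transform — the
skeleton is a Zhang–Suen thinning (guarded against the classical 2×2
annihilation pathology), the distance map comes from EBImage, and the
conversion to µm uses the lateral pitch (in-plane voxels are within 2%
of isotropic at the default geometry). Components touching the lateral
slice edges are excluded from the statistics: cross-sections clipped by
the FOV otherwise bias the diameters low. Records are block-averaged by
centroid on a k×k grid (k = 10), empty cells are filled from their
nearest non-empty cell (the generative process gives no value for an
empty cell, and nearest-fill keeps the subsequent interpolation local),
and the grid is upsampled to the full map size by cubic-convolution
bicubic interpolation (Catmull–Rom kernel, border-replicated), whose
weights sum to one so a constant field stays constant.

A trained segmentation network can replace the classical default by
passing any function with the `segment_lumens()` signature to
`segment_volume()`; the recovery tolerances quoted in the tests (15% on
population means of 20/40/80 µm) are stated for the classical default.

**Stitching** places per-line maps on a shared grid by their origins
(snapped to the nearest cell — adjacent scanlines are generally not an
integer number of cells apart, so snapping trades ≤ half a pixel of
placement for an exact common grid) and averages wherever several lines
are valid.

## Speed sweep

Faster scanning at a fixed frame rate thins the elevational sampling:
`simulate_speed()` keeps every `round(v/v_ref)`-th line and re-expands by
nearest-line replication so the degraded map stays pixelwise comparable.
`quality_score()` normalizes both maps by the original's range and
computes a mean local SSIM with a 7×7 uniform window and the standard
stabilizing constants (C1 = 0.01², C2 = 0.03² on unit range). The scan
time and frame counts scale inversely with speed and are truncated to
whole units, matching how such figures are conventionally quoted.

## Problem sizes and numerical conventions

The test-suite and acceptance studies run the full algorithms on reduced
rasters chosen so each study isolates what it measures: controller
regulation uses the full 700-pixel axial quantization with a 32-column
raster (the NSD only needs the highest surface point); extinction
recovery uses 600 axial pixels so the 1 mm window fits below the surface;
the phantom study uses 10× coarser pixels over a 10 × 14 mm footprint and
three overlapping scanlines; lumen studies keep the native 2.73 µm
lateral pitch (a 20 µm lumen is only ~7 px across) over a ~1 mm² field.
Determinism is enforced by explicit seeds everywhere randomness enters
(scene generation, per-frame speckle streams derived from the scan seed),
and verified by hash-identical pipeline reruns.

Degenerate inputs follow explicit conventions: all-background images
yield an invalid detection (used to terminate landings and skip frames);
invalid extinction fits are NA values, not errors; a single-pixel lumen
component gets one pixel-equivalent of diameter; voxel-boundary points
bin upward; empty DIAM record sets give an all-invalid map.

## Known limitations

- The renderer's simplicity is a feature for verifiability but means
  image-quality effects (defocus away from the working distance, speckle
  decorrelation, shadowing under vessels) do not degrade the maps the way
  they would on hardware.
- The classical lumen segmenter assumes lumens are darker than the
  attenuation-normalized background; low-contrast or bright-rimmed
  structures need a model-based segmenter plugged into the interface.
- DIAM statistics exclude FOV-clipped components, so structures wider
  than the lateral FOV are systematically unmeasurable.
- Orientation servoing (tilting the probe toward the surface normal) and
  tissue-motion compensation are out of scope; the controller only
  regulates altitude.
- Skeleton-based diameters are quantized by the pixel pitch; at 2.73 µm
  per pixel the floor is ~±1 px (≈ 14% of a 20 µm lumen, ≈ 3% of an
  80 µm one).
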