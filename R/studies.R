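#' Closed-loop NSD regulation study on a flat sample
#'
#' Lands on a flat noiseless scene and runs one scanline at the reference
#' speed, reporting how well the controller holds the normalized surface
#' depth at its setpoint. The lateral raster is narrowed (the NSD uses
#' only the highest surface point, so a narrow B-scan measures the same
#' quantity) while the axial raster keeps its full quantization.
#'
#' @param L scanline length, mm.
#' @param v_x scan speed, mm/s.
#' @param n_lateral lateral raster width used for the simulation.
#' @param geom `pixel_geometry`; default keeps the standard axial pitch.
#' @param state `controller_state`.
#' @return List: `hold_frac` (fraction of frames within one axial-pixel
#'   quantization of the setpoint), `n_frames`, `telemetry`.
#' @export
controller_hold_study <- function(L = 50, v_x = 0.6, n_lateral = 32L,
                                  geom = pixel_geometry(n_lateral = n_lateral),
                                  state = controller_state(z_min = -2,
                                                           z_max = 5)) {
  sc <- flat_scene_internal()
  plan <- plan_scanlines(0, 0, 2.5, L = L, W = geom$fov_lateral / 2,
                         W_ol = geom$fov_lateral / 5, geom = geom,
                         v_x = v_x, frame_rate = 20)
  p0 <- land_probe(sc, plan, 1, geom, state, descent_speed = 0.5, dt = 0.02)
  ts <- execute_scanline(sc, plan, 1, geom, state, start_pose = p0,
                         keep_frames = FALSE)
  mu <- ts$telemetry$mu
  list(hold_frac = mean(abs(mu - state$mu_target) <= 1 / geom$n_axial),
       n_frames = length(mu), telemetry = ts$telemetry)
}

flat_scene_internal <- function(mu = 2.0)
  synthetic_scene(extent = c(-100, 100, -100, 100),
                  height_fun = function(x, y) rep(0, length(y)),
                  mu_fun = function(x, y) rep(mu, length(y)))

#' Extinction-coefficient recovery study
#'
#' Renders uniform-attenuation scenes over a grid of ground-truth mu_t
#' values, fits every A-scan with the single-scattering model, and
#' reports the per-mu relative errors.
#'
#' @param mu_values ground-truth extinction coefficients, mm^-1.
#' @param speckle_sd speckle level (0 = noiseless).
#' @param n_ascans A-scans per mu value.
#' @param window_mm fit window, mm.
#' @param seed RNG seed for the speckle.
#' @return Data frame with `mu`, `median_rel_err`, `mean_rel_err`.
#' @export
extinction_recovery_study <- function(mu_values = c(0.5, 1, 2, 4),
                                      speckle_sd = 0, n_ascans = 200L,
                                      window_mm = 1.0, seed = 1L) {
  geom <- pixel_geometry(n_lateral = n_ascans, n_axial = 600L)
  rows <- lapply(seq_along(mu_values), function(i) {
    mu <- mu_values[i]
    sc <- flat_scene_internal(mu = mu)
    p <- pose(diag(c(1, -1, -1)),
              c(0, 0, 0.25 * geom$fov_axial_mm))
    b <- render_bscan(sc, p, geom, speckle_sd = speckle_sd,
                      seed = seed + i)
    det <- detect_surface(b)
    fits <- fit_extinction_frame(b$image, det$surface_rows, geom,
                                 window_mm = window_mm)
    rel <- abs(fits - mu) / mu
    data.frame(mu = mu, median_rel_err = median(rel, na.rm = TRUE),
               mean_rel_err = mean(rel, na.rm = TRUE))
  })
  do.call(rbind, rows)
}

#' Letter-phantom localization accuracy study
#'
#' Scans a letter phantom with three overlapping scanlines, reconstructs
#' the stitched DEPM, and scores the glyph extents against the programmed
#' geometry. Optionally repeats the reconstruction with zero-mean Gaussian
#' jitter injected into the recorded elevational pose coordinate,
#' emulating encoder noise in the scan direction, to compare the
#' elevational and lateral accuracy.
#'
#' @param extrusion_height glyph extrusion, mm.
#' @param v_x scan speed, mm/s.
#' @param jitter_sd elevational pose jitter, mm (0 disables the
#'   Monte-Carlo).
#' @param n_jitter jitter repeats.
#' @param seed RNG seed.
#' @return List: `accuracy` (clean-scan report of
#'   [evaluate_depm_accuracy()]), `depm`, `voxel_size`, and with jitter
#'   `jitter_height_err` / `jitter_width_err` (mean absolute extent errors
#'   over the repeats, mm).
#' @export
phantom_depm_study <- function(extrusion_height = 0.5, v_x = 2.0,
                               jitter_sd = 0, n_jitter = 3L, seed = 1L) {
  geom <- pixel_geometry(res_lateral = 2.73e-2, res_axial = 1.072e-2,
                         n_lateral = 200L, n_axial = 200L)
  sc <- make_letter_phantom(footprint = c(10, 14),
                            extrusion_heights = extrusion_height,
                            glyph_spec = phantom_glyphs(4, glyph_size = c(4, 2.4),
                                                        spacing = 3.2,
                                                        origin = c(3, 1.0)),
                            mu = 2)
  plan <- plan_scanlines(0, 2.8, 3, L = 10, W = 11, W_ol = 1.5,
                         geom = geom, v_x = v_x, frame_rate = 20)
  stopifnot(plan$n == 3L)
  state <- controller_state(z_min = -1, z_max = 5)
  scans <- scan_sample(sc, plan, geom, state)
  vols <- lapply(scans, voxelize_scan)
  stitched <- stitch_maps(lapply(vols, depm))
  out <- list(accuracy = evaluate_depm_accuracy(stitched, sc, pad = 0.5),
              depm = stitched, voxel_size = vols[[1]]$voxel_size)
  if (jitter_sd > 0) {
    errs <- with_local_seed(seed, {
      vapply(seq_len(n_jitter), function(r) {
        jscans <- lapply(scans, function(s) {
          s$poses <- lapply(s$poses, function(p) {
            p$translation[1] <- p$translation[1] + rnorm(1, 0, jitter_sd)
            p
          })
          s
        })
        jm <- stitch_maps(lapply(jscans, function(s) depm(voxelize_scan(s))))
        a <- evaluate_depm_accuracy(jm, sc, pad = 0.5)
        c(a$summary["height_mean"], a$summary["width_mean"])
      }, numeric(2))
    })
    out$jitter_height_err <- mean(errs[1, ])
    out$jitter_width_err <- mean(errs[2, ])
  }
  out
}

#' Lumen-diameter recovery and speed-robustness study
#'
#' For each programmed mean diameter, builds a tubule population in a
#' kidney-like scene, scans one line at full lateral resolution, segments
#' and measures the lumens, and compares the DIAM map mean with the
#' ground-truth population mean. For the reference population it also
#' quantifies speed robustness: the structural-similarity score of the
#' DIAM and of the binary mask top view after elevational downsampling to
#' the maximum speed.
#'
#' @param diameter_means programmed population means, um.
#' @param speckle_sd speckle level of the renderer.
#' @param v_max_ratio speed ratio for the robustness comparison.
#' @param seed RNG seed.
#' @return List: `recovery` data frame (`target_um`, `truth_um`,
#'   `map_mean_um`, `rel_err`), `diam_quality`, `mask_quality` (SSIM at
#'   the accelerated speed).
#' @export
diam_recovery_study <- function(diameter_means = c(20, 40, 80),
                                speckle_sd = 0.2, v_max_ratio = 8.5,
                                seed = 1L) {
  geom <- pixel_geometry(n_lateral = 256L, n_axial = 256L)
  state <- controller_state(z_min = -2, z_max = 5)
  rows <- list(); qual <- NULL
  for (i in seq_along(diameter_means)) {
    dmean <- diameter_means[i]
    sc <- make_kidney_scene(extent = c(0, 1.2, 0, 0.8),
                            relief_amplitude = 0.02, correlation_length = 1,
                            capsule_mu = 2, capsule_thickness = 0.03,
                            parenchyma_mu = 1.5,
                            lumen_density = if (dmean >= 80) 8 else 20,
                            lumen_diameter_mean = dmean,
                            lumen_diameter_sd = 0.1 * dmean,
                            lumen_depth_range = c(0.08, 0.28),
                            seed = seed + 100L * i)
    plan <- plan_scanlines(0.1, 0.4, 3, L = 1.0, W = 0.5, W_ol = 0.2,
                           geom = geom, v_x = 0.2, frame_rate = 20)
    ts <- execute_scanline(sc, plan, 1, geom, state,
                           speckle_sd = speckle_sd, seed = seed + i)
    vol <- voxelize_scan(ts)
    msk <- clean_mask(segment_volume(vol))
    recs <- measure_diameters(msk, pitch_mm = vol$voxel_size[2],
                              origin = vol$origin,
                              voxel_size = vol$voxel_size)
    dm <- diam_map(recs, dims_xy = dim(vol$sums)[1:2],
                   origin_xy = vol$origin[1:2],
                   pitch_xy = vol$voxel_size[1:2], k = 10L)
    truth <- mean(sc$metadata$lumen_diameters_um)
    rows[[i]] <- data.frame(target_um = dmean, truth_um = truth,
                            map_mean_um = mean(dm$values),
                            rel_err = (mean(dm$values) - truth) / truth)
    if (i == 2L || length(diameter_means) == 1L) {
      mm <- parameter_map(mask_top_view(msk),
                          origin_xy = vol$origin[1:2],
                          pitch_xy = vol$voxel_size[1:2], kind = "MASK")
      v_ref <- plan$v_x
      qual <- c(diam_quality = quality_score(
                  simulate_speed(dm, v_max_ratio * v_ref, v_ref), dm),
                mask_quality = quality_score(
                  simulate_speed(mm, v_max_ratio * v_ref, v_ref), mm))
    }
  }
  c(list(recovery = do.call(rbind, rows)), as.list(qual))
}
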