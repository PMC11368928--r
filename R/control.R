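#' Detect the tissue surface in a B-scan
#'
#' Per lateral column, the surface row is the topmost pixel whose intensity
#' lies in the band `[lower, upper]` and that starts a run of at least
#' `m_persist` consecutive in-band pixels. The band's upper bound rejects
#' saturated specular reflections above the true surface; the persistence
#' requirement rejects isolated noise pixels. `h_tis` is the minimum valid
#' surface row: the highest detected point of the tissue.
#'
#' @param image An `oct_bscan` or a numeric matrix (rows = axial).
#' @param lower,upper intensity band, `lower < upper`.
#' @param m_persist minimum run length of in-band pixels.
#' @return List of class `surface_detection`: `surface_rows` (0-based axial
#'   index per column, `NA` where no surface), `h_tis`, and `valid`
#'   (`FALSE` when no column has a surface, i.e. sample not in view).
#' @export
detect_surface <- function(image, lower = 0.15, upper = 0.85, m_persist = 3L) {
  if (inherits(image, "oct_bscan")) image <- image$image
  if (!(lower < upper)) stop("need lower < upper")
  nr <- nrow(image); nc <- ncol(image)
  inb <- image >= lower & image <= upper
  cond <- inb
  if (m_persist > 1L) {
    for (s in seq_len(m_persist - 1L)) {
      shifted <- rbind(inb[-seq_len(s), , drop = FALSE],
                       matrix(FALSE, s, nc))
      cond <- cond & shifted
    }
  }
  any_col <- colSums(cond) > 0L
  first <- rep(NA_integer_, nc)
  if (any(any_col))
    first[any_col] <- apply(cond[, any_col, drop = FALSE], 2L, which.max) - 1L
  h_tis <- if (any(any_col)) min(first, na.rm = TRUE) else NA_integer_
  structure(list(surface_rows = first, h_tis = h_tis, valid = any(any_col)),
            class = "surface_detection")
}

#' Normalized surface depth (NSD)
#'
#' `mu = 1 - h_tis / H_OCT`: 1 when the tissue surface touches the top of
#' the image, approaching 0 as it sinks to the bottom. The probe-altitude
#' controller regulates this quantity to its setpoint (0.75 by default).
#'
#' @param h_tis axial pixel row of the highest detected surface point.
#' @param H_OCT axial field of view in pixels.
#' @return NSD in (0, 1).
#' @export
compute_nsd <- function(h_tis, H_OCT) {
  if (any(h_tis <= 0) || any(h_tis >= H_OCT))
    stop("NSD requires 0 < h_tis < H_OCT")
  1 - h_tis / H_OCT
}

#' Altitude controller state
#'
#' Parameters of the low-pass-filtered proportional controller that keeps
#' the tissue at a fixed normalized depth:
#' `v_z[t] = w_s * K_p * (mu_target - mu) + (1 - w_s) * v_z[t-1]`.
#' A positive controller output commands descent (negative base-frame z
#' velocity). The commanded absolute altitude is clamped to
#' `[z_min, z_max]`.
#'
#' Defaults (`K_p` = 6 mm/s per unit NSD, `w_s` = 0.4) were tuned on the
#' quantized flat-scene step response (see `inst/scripts/tune_controller.R`)
#' so a step of 0.05 NSD settles to within one axial pixel inside 1 s at
#' 20 fps with no overshoot.
#'
#' @param K_p velocity gain, mm/s per unit NSD error.
#' @param w_s low-pass filter weight in [0, 1]; 1 disables filtering.
#' @param mu_target NSD setpoint.
#' @param v_z_prev previous controller output, mm/s.
#' @param z_min,z_max absolute altitude clamp, base-frame mm.
#' @return An object of class `controller_state`.
#' @export
controller_state <- function(K_p = 6.0, w_s = 0.4, mu_target = 0.75,
                             v_z_prev = 0, z_min = -Inf, z_max = Inf) {
  if (w_s < 0 || w_s > 1) stop("w_s must lie in [0, 1]")
  if (!(z_min < z_max)) stop("need z_min < z_max")
  structure(list(K_p = K_p, w_s = w_s, mu_target = mu_target,
                 v_z_prev = v_z_prev, z_min = z_min, z_max = z_max),
            class = "controller_state")
}

#' One controller update
#'
#' @param mu current NSD measurement.
#' @param state A `controller_state`.
#' @return List with `v_z` (controller output, mm/s; positive commands
#'   descent) and the updated `state`.
#' @export
altitude_velocity <- function(mu, state) {
  v_z <- state$w_s * state$K_p * (state$mu_target - mu) +
    (1 - state$w_s) * state$v_z_prev
  state$v_z_prev <- v_z
  list(v_z = v_z, state = state)
}

#' Land the probe onto the sample surface
#'
#' From the entry pose of scanline `i`, descends at a constant velocity in
#' fixed steps, rendering and detecting at each step, and stops at the
#' first step where the surface is detected with NSD at or above the
#' setpoint. Fails if the altitude floor `z_min` is reached without
#' lock-on (e.g. an empty tray).
#'
#' @param scene An `oct_scene`.
#' @param plan A `scan_plan`.
#' @param i scanline index.
#' @param geom A `pixel_geometry`.
#' @param state A `controller_state` (provides `mu_target` and `z_min`).
#' @param descent_speed constant landing velocity, mm/s.
#' @param dt landing step period, s.
#' @param lower,upper,m_persist surface-detection parameters.
#' @param speckle_sd,seed renderer noise controls.
#' @return The lock-on `oct_pose`.
#' @export
land_probe <- function(scene, plan, i, geom, state = controller_state(),
                       descent_speed = 2.0, dt = 0.05,
                       lower = 0.15, upper = 0.85, m_persist = 3L,
                       speckle_sd = 0, seed = NULL) {
  p <- entry_pose(plan, i)
  z <- p$translation[3]
  step <- descent_speed * dt
  k <- 0L
  repeat {
    b <- render_bscan(scene, pose(p$rotation, c(p$translation[1:2], z)),
                      geom, speckle_sd,
                      seed = if (is.null(seed)) NULL else seed + k)
    det <- detect_surface(b, lower, upper, m_persist)
    if (det$valid && det$h_tis > 0 && det$h_tis < geom$n_axial) {
      mu <- compute_nsd(det$h_tis, geom$n_axial)
      if (mu >= state$mu_target)
        return(pose(p$rotation, c(p$translation[1:2], z), k * dt))
    }
    z <- z - step
    k <- k + 1L
    if (z < state$z_min)
      stop("landing failure: altitude floor reached without surface lock-on")
  }
}

#' Execute one scanline with closed-loop altitude regulation
#'
#' Starting from the lock-on pose, the probe advances along x by
#' `v_x / frame_rate` per frame while the controller adjusts the altitude
#' from the NSD measured in each rendered B-scan. Frames with no valid
#' surface detection hold the last valid NSD so the low-pass-filtered
#' command decays smoothly instead of jumping. Altitude is clamped to
#' `[z_min, z_max]` at every step. The line stops after travelling `L`
#' (`ceiling(L * frame_rate / v_x)` frames).
#'
#' @param scene An `oct_scene`.
#' @param plan A `scan_plan`.
#' @param i scanline index.
#' @param geom A `pixel_geometry`.
#' @param state A `controller_state`.
#' @param speckle_sd,seed renderer noise controls; the seed also fixes the
#'   per-frame speckle streams, making the scan reproducible.
#' @param start_pose optional lock-on pose; when `NULL`, [land_probe()] is
#'   run first.
#' @param lower,upper,m_persist surface-detection parameters.
#' @param keep_frames keep the rendered images (set `FALSE` to retain only
#'   telemetry).
#' @return An object of class `tracked_scan`: `frames` (list of matrices),
#'   `poses` (list of `oct_pose`), `geom`, and `telemetry` (data frame with
#'   per-frame `t_s, x_mm, z_mm, mu, v_z, valid`).
#' @export
execute_scanline <- function(scene, plan, i, geom, state = controller_state(),
                             speckle_sd = 0, seed = NULL, start_pose = NULL,
                             lower = 0.15, upper = 0.85, m_persist = 3L,
                             keep_frames = TRUE) {
  if (is.null(start_pose))
    start_pose <- land_probe(scene, plan, i, geom, state,
                             lower = lower, upper = upper,
                             m_persist = m_persist,
                             speckle_sd = speckle_sd, seed = seed)
  n_frames <- as.integer(ceiling(plan$L * plan$frame_rate / plan$v_x))
  pitch <- plan$v_x / plan$frame_rate
  z <- start_pose$translation[3]
  y <- start_pose$translation[2]
  x0 <- start_pose$translation[1]
  frames <- if (keep_frames) vector("list", n_frames) else NULL
  poses <- vector("list", n_frames)
  tele <- data.frame(t_s = numeric(n_frames), x_mm = numeric(n_frames),
                     z_mm = numeric(n_frames), mu = numeric(n_frames),
                     v_z = numeric(n_frames), valid = logical(n_frames))
  mu_last <- state$mu_target
  for (t in seq_len(n_frames)) {
    x <- x0 + (t - 1) * pitch
    p <- pose(diag(c(1, -1, -1)), c(x, y, z), (t - 1) / plan$frame_rate)
    fseed <- if (is.null(seed)) NULL
             else (seed + 97003L * i + 7919L * t) %% 2147483647L
    b <- render_bscan(scene, p, geom, speckle_sd, seed = fseed)
    det <- detect_surface(b, lower, upper, m_persist)
    ok <- det$valid && !is.na(det$h_tis) &&
      det$h_tis > 0 && det$h_tis < geom$n_axial
    mu <- if (ok) compute_nsd(det$h_tis, geom$n_axial) else mu_last
    upd <- altitude_velocity(mu, state)
    state <- upd$state
    if (keep_frames) frames[[t]] <- b$image
    poses[[t]] <- p
    tele[t, ] <- list((t - 1) / plan$frame_rate, x, z, mu, upd$v_z, ok)
    mu_last <- mu
    # positive controller output = descend; explicit Euler at the frame rate
    z <- min(max(z - upd$v_z / plan$frame_rate, state$z_min), state$z_max)
  }
  structure(list(frames = frames, poses = poses, geom = geom,
                 telemetry = tele, line = i, plan = plan,
                 speckle_sd = speckle_sd, seed = seed),
            class = "tracked_scan")
}

#' @export
print.tracked_scan <- function(x, ...) {
  cat(sprintf("<tracked_scan> line %d: %d frame(s), %d x %d px\n",
              x$line, length(x$poses), x$geom$n_axial, x$geom$n_lateral))
  invisible(x)
}
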