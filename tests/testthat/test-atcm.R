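test_that("noiseless extinction fits recover mu exactly", {
  geom <- small_geom()
  for (mu in c(0.5, 1, 2, 4)) {
    sc <- flat_scene(mu = mu)
    b <- render_bscan(sc, standoff_pose(geom), geom)
    det <- detect_surface(b)
    fit <- fit_extinction(b$image[, 20], det$surface_rows[20], geom,
                          window_mm = 0.35)
    expect_equal(fit, mu, tolerance = 1e-6)
  }
})

test_that("degenerate A-scans are handled as specified", {
  geom <- small_geom()
  # constant intensity: zero slope, mu = 0
  expect_equal(fit_extinction(rep(0.5, 200), 20, geom, window_mm = 0.35), 0)
  # invalid surface propagates as an invalid (NA) fit, not an error
  expect_true(is.na(fit_extinction(rep(0.5, 200), NA, geom)))
  # too few usable samples below the floor
  a <- rep(1e-9, 200)
  expect_true(is.na(fit_extinction(a, 10, geom, window_mm = 0.35)))
})

test_that("speckled extinction recovery stays within 10% in the median", {
  geom <- small_geom(n_lateral = 100L, n_axial = 420L)
  sc <- flat_scene(mu = 2.0)
  b <- render_bscan(sc, standoff_pose(geom), geom, speckle_sd = 0.2,
                    seed = 21)
  det <- detect_surface(b)
  fits <- roctscan:::fit_extinction_frame(b$image, det$surface_rows, geom,
                                          window_mm = 1.0)
  rel <- abs(fits - 2.0) / 2.0
  expect_lt(median(rel, na.rm = TRUE), 0.10)
})

test_that("the vectorized frame fit agrees with the per-column fit", {
  geom <- small_geom(n_lateral = 12L)
  sc <- flat_scene(mu = 1.5)
  b <- render_bscan(sc, standoff_pose(geom), geom, speckle_sd = 0.15,
                    seed = 4)
  det <- detect_surface(b)
  vec <- roctscan:::fit_extinction_frame(b$image, det$surface_rows, geom,
                                         window_mm = 0.3)
  for (j in c(1, 5, 12))
    expect_equal(vec[j], fit_extinction(b$image[, j], det$surface_rows[j],
                                        geom, window_mm = 0.3),
                 tolerance = 1e-9)
})

test_that("a uniform scene yields a constant ATCM on the pose grid", {
  geom <- small_geom(n_lateral = 40L, n_axial = 300L)
  sc <- flat_scene(mu = 1.5)
  plan <- plan_scanlines(0, 0, 0.6, L = 0.5, W = 0.1, W_ol = 0.04,
                         geom = geom, v_x = 1, frame_rate = 20)
  st <- controller_state(z_min = -1, z_max = 2)
  ts <- execute_scanline(sc, plan, 1, geom, st)
  m <- atcm(ts, window_mm = 0.5)
  expect_equal(m$kind, "ATCM")
  expect_gt(mean(m$valid), 0.95)
  expect_equal(mean(m$values[m$valid]), 1.5, tolerance = 0.02)
  expect_lt(sd(m$values[m$valid]), 0.05)
  expect_equal(m$pitch_xy[1], plan$pitch_elev, tolerance = 1e-9)
})

test_that("a low-attenuation tube appears as a streak at the right place", {
  geom <- small_geom(n_lateral = 80L, n_axial = 300L)
  sc <- flat_scene(mu = 2.0)
  # tube along x at y = +0.05 mm, just below the surface
  sc$ellipsoids <- data.frame(cx = 0, cy = 0.05, cz = -0.12, ax = 10,
                              ay = 0.035, az = 0.035, mu = 0.3,
                              backscatter = 1, is_lumen = FALSE)
  plan <- plan_scanlines(-0.2, 0, 0.6, L = 0.4, W = 0.15, W_ol = 0.06,
                         geom = geom, v_x = 1, frame_rate = 20)
  st <- controller_state(z_min = -1, z_max = 2)
  ts <- execute_scanline(sc, plan, 1, geom, st)
  m <- atcm(ts, window_mm = 0.5)
  ys <- m$origin_xy[2] + (seq_len(ncol(m$values)) - 0.5) * m$pitch_xy[2]
  prof <- colMeans(m$values, na.rm = TRUE)
  # the minimum of the lateral profile sits within 2 map pixels of the tube
  expect_lt(abs(ys[which.min(prof)] - 0.05), 2 * m$pitch_xy[2])
  expect_lt(min(prof), 1.9)
  expect_equal(max(prof), 2.0, tolerance = 0.05)
})

test_that("two-region scenes separate by far more than their standard errors", {
  geom <- small_geom(n_lateral = 60L, n_axial = 300L)
  sc <- synthetic_scene(extent = c(-5, 5, -5, 5),
                        height_fun = function(x, y) rep(0, length(y)),
                        mu_fun = function(x, y) ifelse(y < 0, 1.0, 3.0))
  plan <- plan_scanlines(0, 0, 0.6, L = 0.3, W = 0.1, W_ol = 0.04,
                         geom = geom, v_x = 1, frame_rate = 20)
  st <- controller_state(z_min = -1, z_max = 2)
  ts <- execute_scanline(sc, plan, 1, geom, st, speckle_sd = 0.2, seed = 3)
  m <- atcm(ts, window_mm = 0.5)
  ys <- m$origin_xy[2] + (seq_len(ncol(m$values)) - 0.5) * m$pitch_xy[2]
  lo <- m$values[, ys < -0.01]; hi <- m$values[, ys > 0.01]
  se <- function(v) sd(v, na.rm = TRUE) / sqrt(sum(is.finite(v)))
  gap <- mean(hi, na.rm = TRUE) - mean(lo, na.rm = TRUE)
  expect_gt(gap, 5 * (se(lo) + se(hi)))
})
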