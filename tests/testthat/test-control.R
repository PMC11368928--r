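test_that("surface detection finds a rendered flat surface at the known row", {
  geom <- small_geom()
  sc <- flat_scene()
  standoff <- 100 * geom$res_axial            # surface exactly at row 100
  b <- render_bscan(sc, pose(diag(c(1, -1, -1)), c(0, 0, standoff)), geom)
  det <- detect_surface(b)
  expect_true(det$valid)
  expect_identical(det$h_tis, 100L)
  expect_true(all(det$surface_rows == 100L, na.rm = TRUE))
})

test_that("a pure-background image yields an invalid detection", {
  det <- detect_surface(matrix(0.02, 50, 8))
  expect_false(det$valid)
  expect_true(is.na(det$h_tis))
})

test_that("saturated reflections above the surface are skipped", {
  img <- matrix(0.02, 60, 5)
  img[20, ] <- 0.99                 # specular reflection, above the band
  img[35:60, ] <- 0.5               # true tissue
  det <- detect_surface(img, lower = 0.15, upper = 0.85)
  expect_identical(det$h_tis, 34L)  # 0-based row of the tissue start
  # without an upper bound the reflection would win
  det2 <- detect_surface(img, lower = 0.15, upper = 1.0, m_persist = 1L)
  expect_identical(det2$h_tis, 19L)
})

test_that("isolated in-band pixels are rejected by persistence", {
  img <- matrix(0.02, 60, 3)
  img[10, 2] <- 0.5                 # lone speck
  img[40:60, ] <- 0.5
  det <- detect_surface(img, m_persist = 3L)
  expect_identical(det$h_tis, 39L)
})

test_that("NSD follows its definition and domain", {
  expect_equal(compute_nsd(175, 700), 0.75)
  expect_equal(compute_nsd(350, 700), 0.5)
  expect_equal(compute_nsd(699, 700), 1 - 699 / 700)
  expect_error(compute_nsd(0, 700), "h_tis")
  expect_error(compute_nsd(700, 700), "h_tis")
})

test_that("the controller law reproduces the filtered proportional form", {
  st <- controller_state(K_p = 2, w_s = 1, mu_target = 0.75)
  expect_equal(altitude_velocity(0.75, st)$v_z, 0)
  expect_equal(abs(altitude_velocity(0.5, st)$v_z), 0.5)
  # w_s = 0: output sticks to the previous command regardless of mu
  st0 <- controller_state(K_p = 2, w_s = 0, v_z_prev = 0.3)
  expect_equal(altitude_velocity(0.1, st0)$v_z, 0.3)
  expect_equal(altitude_velocity(0.9, st0)$v_z, 0.3)
  # general recursion
  st2 <- controller_state(K_p = 4, w_s = 0.3, mu_target = 0.75,
                          v_z_prev = -0.2)
  expect_equal(altitude_velocity(0.6, st2)$v_z,
               0.3 * 4 * 0.15 + 0.7 * -0.2)
})

test_that("the instantaneous correction is scale-equivariant in K_p", {
  a <- altitude_velocity(0.6, controller_state(K_p = 2, w_s = 1))$v_z
  b <- altitude_velocity(0.6, controller_state(K_p = 4, w_s = 1))$v_z
  expect_equal(b, 2 * a)
})

test_that("commanded altitude never leaves the clamp on adversarial input", {
  set.seed(99)
  geom <- small_geom()
  st <- controller_state(K_p = 50, w_s = 1, z_min = 0.2, z_max = 0.6)
  z <- 0.4
  for (mu in runif(200, 0.01, 0.99)) {
    upd <- altitude_velocity(mu, st)
    st <- upd$state
    z <- min(max(z - upd$v_z / 20, st$z_min), st$z_max)
    expect_gte(z, st$z_min)
    expect_lte(z, st$z_max)
  }
})

test_that("landing locks on close to the NSD setpoint", {
  geom <- small_geom()
  sc <- flat_scene()
  plan <- plan_scanlines(0, 0, 1.0, L = 1, W = 0.15, W_ol = 0.05,
                         geom = geom, v_x = 1)
  st <- controller_state(z_min = -1, z_max = 2)
  # fine steps: lock-on NSD converges to the setpoint from above in
  # altitude (the landing stops at the first step where mu >= target)
  p <- land_probe(sc, plan, 1, geom, st, descent_speed = 0.5, dt = 0.02)
  det <- detect_surface(render_bscan(sc, p, geom))
  mu <- compute_nsd(det$h_tis, geom$n_axial)
  expect_gte(mu, 0.75)
  step_nsd <- 0.5 * 0.02 / geom$fov_axial_mm
  expect_lte(mu, 0.75 + step_nsd + 1 / geom$n_axial)
  # analytic lock-on altitude: surface within one step of 0.25 * FOV
  expect_lte(abs(p$translation[3] - 0.25 * geom$fov_axial_mm), 0.5 * 0.02 + 1e-9)
})

test_that("landing over an empty tray fails at the altitude floor", {
  geom <- small_geom()
  empty <- synthetic_scene(extent = c(-50, 50, -50, 50),
                           height_fun = function(x, y) rep(-100, length(y)))
  plan <- plan_scanlines(0, 0, 1, L = 1, W = 0.15, W_ol = 0.05,
                         geom = geom, v_x = 1)
  st <- controller_state(z_min = -0.5, z_max = 2)
  expect_error(land_probe(empty, plan, 1, geom, st), "landing failure")
})

test_that("a scanline acquires ceiling(L * fps / v_x) frames", {
  geom <- small_geom(n_lateral = 16L)
  sc <- flat_scene()
  plan <- plan_scanlines(0, 0, 1, L = 1.3, W = 0.04, W_ol = 0.01,
                         geom = geom, v_x = 2, frame_rate = 20)
  st <- controller_state(z_min = -1, z_max = 2)
  ts <- execute_scanline(sc, plan, 1, geom, st)
  expect_length(ts$frames, ceiling(1.3 * 20 / 2))
  expect_equal(ts$telemetry$x_mm[2] - ts$telemetry$x_mm[1], 2 / 20)
})

test_that("the closed loop holds NSD on a flat scene", {
  geom <- small_geom(n_lateral = 24L)
  sc <- flat_scene()
  plan <- plan_scanlines(0, 0, 1, L = 20, W = 0.06, W_ol = 0.02,
                         geom = geom, v_x = 1, frame_rate = 20)
  st <- controller_state(z_min = -1, z_max = 2)
  p0 <- land_probe(sc, plan, 1, geom, st, descent_speed = 0.5, dt = 0.02)
  ts <- execute_scanline(sc, plan, 1, geom, st, start_pose = p0)
  mu <- ts$telemetry$mu
  expect_gt(mean(abs(mu - 0.75) <= 1 / geom$n_axial), 0.95)
})

test_that("ramp tracking shows the predicted steady-state NSD offset", {
  geom <- small_geom(n_lateral = 24L)
  slope <- 0.04                      # mm of rise per mm of travel
  sc <- ramp_scene(slope = slope)
  plan <- plan_scanlines(-20, 0, 1, L = 30, W = 0.06, W_ol = 0.02,
                         geom = geom, v_x = 2, frame_rate = 20)
  st <- controller_state(z_min = -5, z_max = 5)
  ts <- execute_scanline(sc, plan, 1, geom, st)
  mu <- ts$telemetry$mu
  # discrete proportional tracking of a ramp leaves a constant lag:
  # the climb rate slope * v_x must equal K_p * (NSD error) at steady state
  predicted <- slope * plan$v_x / st$K_p
  tail_mu <- tail(mu, 100)
  expect_equal(mean(0.75 - tail_mu), predicted, tolerance = 0.3)
  # the surface stays well inside the image throughout
  expect_true(all(mu > 0.2 & mu < 0.99))
})

test_that("frames losing the surface hold the last valid NSD", {
  geom <- small_geom(n_lateral = 16L)
  # surface drops off a cliff into the void half way along the line
  cliff <- synthetic_scene(extent = c(-50, 50, -50, 50),
                           height_fun = function(x, y)
                             rep(if (x < 0.5) 0 else -100, length(y)))
  plan <- plan_scanlines(0, 0, 1, L = 1, W = 0.04, W_ol = 0.01,
                         geom = geom, v_x = 2, frame_rate = 20)
  st <- controller_state(z_min = -1, z_max = 2)
  ts <- execute_scanline(cliff, plan, 1, geom, st)
  expect_true(any(!ts$telemetry$valid))
  lastv <- max(which(ts$telemetry$valid))
  after <- ts$telemetry$mu[(lastv + 1):nrow(ts$telemetry)]
  expect_true(all(after == ts$telemetry$mu[lastv]))
})
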