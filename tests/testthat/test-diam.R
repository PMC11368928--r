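test_that("a dark ellipse under tissue is segmented with IoU >= 0.6", {
  geom <- small_geom(n_lateral = 160L, n_axial = 220L)
  # tubule cross-section 60 x 60 um at 0.12 mm depth
  sc <- flat_scene()
  sc$ellipsoids <- data.frame(cx = 0, cy = 0, cz = -0.12, ax = 5,
                              ay = 0.03, az = 0.03, mu = 0.2,
                              backscatter = 0.05, is_lumen = TRUE)
  p <- standoff_pose(geom)
  b <- render_bscan(sc, p, geom)
  m <- segment_lumens(b$image)
  rows <- 0:(geom$n_axial - 1); cols <- 0:(geom$n_lateral - 1)
  yb <- -(cols - (geom$n_lateral - 1) / 2) * geom$res_lateral
  zb <- p$translation[3] - rows * geom$res_axial
  gt <- outer(zb, yb, function(z, y) (y / 0.03)^2 + ((z + 0.12) / 0.03)^2 < 1)
  expect_gte(sum(m & gt) / sum(m | gt), 0.6)
})

test_that("lumen-free slices give an empty mask", {
  geom <- small_geom(n_lateral = 60L)
  b <- render_bscan(flat_scene(), standoff_pose(geom), geom)
  expect_false(any(segment_lumens(b$image)))
  # dark background above the surface is never segmented
  bg <- render_bscan(flat_scene(), standoff_pose(geom, frac = 0.6), geom)
  m <- segment_lumens(bg$image)
  det <- detect_surface(bg$image)
  above <- row(m) - 1 < matrix(det$surface_rows, nrow(m), ncol(m),
                               byrow = TRUE)
  expect_false(any(m & above))
})

test_that("area morphology follows the closing-then-opening contract", {
  # solid disc larger than A_o is unchanged
  disc <- outer(1:30, 1:30, function(i, j) (i - 15)^2 + (j - 15)^2 <= 64)
  expect_identical(clean_mask(disc, 20, 20), disc)
  # a speck smaller than A_o is removed
  speck <- matrix(FALSE, 10, 10); speck[4:5, 4:5] <- TRUE
  expect_false(any(clean_mask(speck, 20, 20)))
  # a pinhole smaller than A_c is filled (10 x 10 oracle fixture)
  holed <- matrix(TRUE, 10, 10); holed[5, 5] <- FALSE
  expect_true(all(clean_mask(holed, 20, 20)))
  # a hole at least A_c stays open
  big <- matrix(TRUE, 30, 30); big[10:20, 10:20] <- FALSE
  expect_false(all(clean_mask(big, 20, 500)))
  # output is a subset of the closed input
  set.seed(8)
  noisy <- matrix(runif(400) < 0.4, 20, 20)
  closed <- roctscan:::area_closing_slice(noisy, 20)
  expect_true(all(closed[clean_mask(noisy, 20, 20)]))
})

test_that("skeleton-based diameters match the distance-transform oracle", {
  # rasterized disc of radius 10 px at 2.73 um/px -> 54.6 um
  disc <- outer(1:41, 1:41, function(i, j) (i - 21)^2 + (j - 21)^2 <= 100)
  rec <- measure_diameters(disc, pitch_mm = 2.73e-3)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$diameter_um, 54.6, tolerance = 2.73 / 54.6)
  # a 1-pixel component gets one pixel equivalent
  px1 <- matrix(FALSE, 9, 9); px1[5, 5] <- TRUE
  expect_equal(measure_diameters(px1, pitch_mm = 2.73e-3)$diameter_um, 2.73)
  # two disjoint discs give two independent records
  two <- matrix(FALSE, 40, 80)
  two[which(outer(1:40, 1:80, function(i, j)
    (i - 20)^2 + (j - 20)^2 <= 36))] <- TRUE
  two[which(outer(1:40, 1:80, function(i, j)
    (i - 20)^2 + (j - 60)^2 <= 144))] <- TRUE
  rec2 <- measure_diameters(two, pitch_mm = 1e-3)
  expect_equal(nrow(rec2), 2L)
  expect_equal(sort(rec2$diameter_um), c(12, 24), tolerance = 0.1)
})

test_that("an elongated ribbon measures its width, not its length", {
  rib <- matrix(FALSE, 15, 60); rib[6:10, 5:55] <- TRUE   # 5 px wide
  rec <- measure_diameters(rib, pitch_mm = 1e-3)
  expect_equal(rec$diameter_um, 5, tolerance = 0.35)
})

test_that("diam_map block-averages by centroid and upsamples smoothly", {
  # two lateral halves with diameters 20 and 40 um
  recs <- data.frame(slice = 1, component = 1:40,
                     cx = runif(40, 0, 1),
                     cy = c(runif(20, 0, 0.5), runif(20, 0.5, 1)),
                     diameter_um = rep(c(20, 40), each = 20),
                     area_px = 50)
  m <- diam_map(recs, dims_xy = c(50, 50), origin_xy = c(0, 0),
                pitch_xy = c(0.02, 0.02), k = 2)
  left <- mean(m$values[, 1:10]); right <- mean(m$values[, 41:50])
  expect_equal(left, 20, tolerance = 0.05 * 20)
  expect_equal(right, 40, tolerance = 0.05 * 40)
  # all lumens identical -> constant map (bicubic of a constant)
  recs$diameter_um <- 30
  mc <- diam_map(recs, dims_xy = c(50, 50), origin_xy = c(0, 0),
                 pitch_xy = c(0.02, 0.02), k = 10)
  expect_equal(range(mc$values), c(30, 30), tolerance = 1e-9)
  # k = 1 gives the global mean everywhere
  recs$diameter_um <- rep(c(20, 40), each = 20)
  m1 <- diam_map(recs, dims_xy = c(50, 50), origin_xy = c(0, 0),
                 pitch_xy = c(0.02, 0.02), k = 1)
  expect_equal(range(m1$values), c(30, 30), tolerance = 1e-9)
})

test_that("no lumens at all produces an all-invalid map", {
  empty <- measure_diameters(matrix(FALSE, 5, 5), pitch_mm = 1e-3)
  m <- diam_map(empty, dims_xy = c(10, 10), origin_xy = c(0, 0),
                pitch_xy = c(0.1, 0.1))
  expect_false(any(m$valid))
})

test_that("segmentation through the volume recovers tube cross-sections", {
  geom <- small_geom(n_lateral = 160L, n_axial = 220L)
  sc <- make_kidney_scene(extent = c(0, 0.6, -0.25, 0.25),
                          relief_amplitude = 0, base_z = 0,
                          capsule_mu = 2, capsule_thickness = 0.03,
                          parenchyma_mu = 1.5, lumen_density = 20,
                          lumen_diameter_mean = 50, lumen_diameter_sd = 4,
                          lumen_depth_range = c(0.1, 0.25), seed = 31)
  plan <- plan_scanlines(0.15, 0, 0.6, L = 0.3, W = 0.3, W_ol = 0.12,
                         geom = geom, v_x = 1, frame_rate = 20)
  st <- controller_state(z_min = -1, z_max = 2)
  ts <- execute_scanline(sc, plan, 1, geom, st)
  vol <- voxelize_scan(ts)
  msk <- clean_mask(segment_volume(vol), 20, 20)
  recs <- measure_diameters(msk, pitch_mm = vol$voxel_size[2],
                            origin = vol$origin,
                            voxel_size = vol$voxel_size)
  expect_gt(nrow(recs), 0)
  expect_equal(mean(recs$diameter_um),
               mean(sc$metadata$lumen_diameters_um), tolerance = 0.15)
})
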