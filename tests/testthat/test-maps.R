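# helper: direct volume with a known surface per (x, y) column
volume_with_surface <- function(nx, ny, nz, surf_k, vz = 0.01) {
  vol <- roctscan:::new_tissue_volume(c(nx, ny, nz), c(0, 0, 0),
                                      c(0.1, 0.1, vz))
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    k <- surf_k[i, j]
    fill <- seq_len(k)                      # tissue from the bottom up to k
    vol$sums[i, j, fill] <- 0.5
    vol$counts[i, j, fill] <- 1L
  }
  vol
}

test_that("depm reads the topmost in-band voxel altitude", {
  surf <- matrix(10L, 4, 5); surf[2, 3] <- 14L
  vol <- volume_with_surface(4, 5, 20, surf)
  m <- depm(vol, lower = 0.2, upper = 0.9)
  expect_true(all(m$valid))
  expect_equal(m$values[1, 1], (10 - 0.5) * 0.01)
  expect_equal(m$values[2, 3], (14 - 0.5) * 0.01)
  expect_equal(m$kind, "DEPM")
})

test_that("depm marks empty columns invalid and rejects empty volumes", {
  surf <- matrix(10L, 3, 3)
  vol <- volume_with_surface(3, 3, 20, surf)
  vol$sums[2, 2, ] <- 0; vol$counts[2, 2, ] <- 0L
  m <- depm(vol, lower = 0.2, upper = 0.9)
  expect_false(m$valid[2, 2])
  expect_true(is.na(m$values[2, 2]))
  expect_true(all(m$valid[-5]))    # linear index of cell (2, 2)
})

test_that("depm of a letter-phantom scan recovers extrusion heights", {
  geom <- coarse_geom(n_lateral = 120L)
  bar <- list(list(name = "bar", strokes = list(c(0.8, 2.2, 0.7, 2.1))))
  sc <- make_letter_phantom(footprint = c(3, 2.8), extrusion_heights = 0.5,
                            glyph_spec = bar, mu = 2)
  plan <- plan_scanlines(0, 1.4, 4, L = 3, W = 2, W_ol = 0.8, geom = geom,
                         v_x = 2, frame_rate = 20)
  st <- controller_state(z_min = -1, z_max = 5)
  ts <- execute_scanline(sc, plan, 1, geom, st)
  vol <- voxelize_scan(ts)
  m <- depm(vol)
  xs <- m$origin_xy[1] + (seq_len(nrow(m$values)) - 0.5) * m$pitch_xy[1]
  ys <- m$origin_xy[2] + (seq_len(ncol(m$values)) - 0.5) * m$pitch_xy[2]
  on_bar <- m$values[xs > 1.0 & xs < 2.0, ys > 0.9 & ys < 1.9]
  off_bar <- m$values[xs < 0.6, ys > 0.9 & ys < 1.9]
  expect_equal(mean(on_bar, na.rm = TRUE), 0.5,
               tolerance = 2 * vol$voxel_size[3] / 0.5)
  expect_lt(abs(mean(off_bar, na.rm = TRUE)), 2 * vol$voxel_size[3])
})

test_that("phantom accuracy is perfect for a synthetic ideal map", {
  sc <- make_letter_phantom(footprint = c(20, 14), extrusion_heights = 0.5,
                            glyph_spec = phantom_glyphs(2))
  pitch <- c(0.05, 0.05)
  xs <- seq(0.025, 19.975, by = 0.05)
  ys <- seq(0.025, 13.975, by = 0.05)
  vals <- t(vapply(xs, function(x) scene_height(sc, x, ys),
                   numeric(length(ys))))
  m <- parameter_map(vals, origin_xy = c(0, 0), pitch_xy = pitch,
                     kind = "DEPM")
  acc <- evaluate_depm_accuracy(m, sc)
  expect_true(all(!acc$per_glyph$missing))
  # extents measured on the sampling lattice are exact to one cell
  expect_lte(max(acc$per_glyph$err_x), pitch[1] + 1e-9)
  expect_lte(max(acc$per_glyph$err_y), pitch[2] + 1e-9)
})

test_that("a lateral shift does not change measured extents", {
  sc <- make_letter_phantom(footprint = c(20, 14), extrusion_heights = 0.5,
                            glyph_spec = phantom_glyphs(2))
  xs <- seq(0.025, 19.975, by = 0.05)
  ys <- seq(0.025, 13.975, by = 0.05)
  vals <- t(vapply(xs, function(x) scene_height(sc, x, ys),
                   numeric(length(ys))))
  m0 <- parameter_map(vals, origin_xy = c(0, 0), pitch_xy = c(0.05, 0.05),
                      kind = "DEPM")
  m1 <- parameter_map(vals, origin_xy = c(0, 0.2), pitch_xy = c(0.05, 0.05),
                      kind = "DEPM")
  a0 <- evaluate_depm_accuracy(m0, sc)
  a1 <- evaluate_depm_accuracy(m1, sc)
  expect_equal(a1$per_glyph$meas_y, a0$per_glyph$meas_y)
})

test_that("a glyph absent from the map is reported missing", {
  sc <- make_letter_phantom(footprint = c(20, 14), extrusion_heights = 0.5,
                            glyph_spec = phantom_glyphs(2))
  vals <- matrix(0, 40, 28)      # flat map: no extrusions at all
  m <- parameter_map(vals, origin_xy = c(0, 0), pitch_xy = c(0.5, 0.5),
                     kind = "DEPM")
  acc <- evaluate_depm_accuracy(m, sc)
  expect_true(all(acc$per_glyph$missing))
})

test_that("stitching averages the overlap and is permutation-invariant", {
  v1 <- parameter_map(matrix(1, 4, 6), origin_xy = c(0, 0),
                      pitch_xy = c(1, 1), kind = "ATCM")
  v3 <- parameter_map(matrix(3, 4, 6), origin_xy = c(0, 4),
                      pitch_xy = c(1, 1), kind = "ATCM")
  s <- stitch_maps(list(v1, v3))
  expect_equal(dim(s$values), c(4L, 10L))
  expect_equal(s$values[1, 5], 2)       # overlap cell: mean of 1 and 3
  expect_equal(s$values[1, 1], 1)
  expect_equal(s$values[1, 10], 3)
  s2 <- stitch_maps(list(v3, v1))
  expect_equal(s2$values, s$values)
  # two identical overlapping maps reproduce the input
  twin <- stitch_maps(list(v1, v1))
  expect_equal(twin$values, v1$values)
})

test_that("stitching rejects inconsistent inputs", {
  a <- parameter_map(matrix(1, 2, 2), origin_xy = c(0, 0),
                     pitch_xy = c(1, 1), kind = "ATCM")
  b <- parameter_map(matrix(1, 2, 2), origin_xy = c(0, 0),
                     pitch_xy = c(2, 2), kind = "ATCM")
  d <- parameter_map(matrix(1, 2, 2), origin_xy = c(0, 0),
                     pitch_xy = c(1, 1), kind = "DEPM")
  expect_error(stitch_maps(list(a, b)), "pitch")
  expect_error(stitch_maps(list(a, d)), "kind")
})
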