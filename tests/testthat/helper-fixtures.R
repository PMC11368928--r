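# Shared scaled-down fixtures: small rasters keep unit tests fast while
# preserving the axial/lateral pitch ratios of the full-size system.

small_geom <- function(n_lateral = 64L, n_axial = 200L)
  pixel_geometry(res_lateral = 2.73e-3, res_axial = 2.68e-3,
                 n_lateral = n_lateral, n_axial = n_axial)

# coarse geometry: 10x the pitch, used where a wide footprint is scanned
coarse_geom <- function(n_lateral = 200L, n_axial = 220L)
  pixel_geometry(res_lateral = 2.73e-2, res_axial = 1.072e-2,
                 n_lateral = n_lateral, n_axial = n_axial)

flat_scene <- function(mu = 2.0, z0 = 0, ...)
  synthetic_scene(extent = c(-50, 50, -50, 50),
                  height_fun = function(x, y) rep(z0, length(y)),
                  mu_fun = function(x, y) rep(mu, length(y)), ...)

ramp_scene <- function(slope = 0.02, mu = 2.0)
  synthetic_scene(extent = c(-50, 50, -50, 50),
                  height_fun = function(x, y) rep(slope * x, length(y)),
                  mu_fun = function(x, y) rep(mu, length(y)))

# pose looking straight down with the B-scan surface row at frac * n_axial
standoff_pose <- function(geom, scene_z = 0, frac = 0.25, x = 0, y = 0)
  pose(diag(c(1, -1, -1)),
       c(x, y, scene_z + frac * geom$n_axial * geom$res_axial))

random_pose <- function() {
  # QR of a random matrix, sign-fixed to det +1
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  pose(q, rnorm(3, sd = 20), runif(1))
}
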