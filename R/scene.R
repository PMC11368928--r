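# Separable Gaussian smoothing with replicated edges; works on lattices
# smaller than the kernel (unlike FFT-based blurs).
gauss_smooth <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth1 <- function(v) {
    vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
    as.numeric(stats::filter(vp, k, sides = 2))[(r + 1):(r + length(v))]
  }
  m <- apply(m, 2L, smooth1)
  t(apply(m, 1L, smooth1))
}

# Evaluate code with a locally set RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Bilinear interpolation closure over a regular grid. Z is nx x ny sampled at
# xs (ascending) and ys (ascending); evaluation clamps to the grid edge.
bilinear_grid <- function(xs, ys, Z) {
  nx <- length(xs); ny <- length(ys)
  function(x, y) {
    x <- min(max(x, xs[1]), xs[nx])
    y <- pmin(pmax(y, ys[1]), ys[ny])
    ix <- pmin(pmax(findInterval(x, xs), 1L), nx - 1L)
    iy <- pmin(pmax(findInterval(y, ys), 1L), ny - 1L)
    fx <- (x - xs[ix]) / (xs[ix + 1L] - xs[ix])
    fy <- (y - ys[iy]) / (ys[iy + 1L] - ys[iy])
    z00 <- Z[cbind(ix, iy)];     z01 <- Z[cbind(ix, iy + 1L)]
    z10 <- Z[cbind(ix + 1L, iy)]; z11 <- Z[cbind(ix + 1L, iy + 1L)]
    (1 - fx) * ((1 - fy) * z00 + fy * z01) + fx * ((1 - fy) * z10 + fy * z11)
  }
}

empty_ellipsoids <- function() {
  data.frame(cx = numeric(0), cy = numeric(0), cz = numeric(0),
             ax = numeric(0), ay = numeric(0), az = numeric(0),
             theta = numeric(0), mu = numeric(0), backscatter = numeric(0),
             is_lumen = logical(0))
}

# Accept ellipsoid tables written before the horizontal-azimuth column.
normalize_ellipsoids <- function(ell) {
  if (is.null(ell$theta)) ell$theta <- rep(0, nrow(ell))
  ell
}

#' Construct a synthetic OCT scene
#'
#' A scene is the virtual sample imaged by the renderer: a surface height
#' field z(x, y) over a rectangular footprint, a layered attenuation model
#' (capsule stratum of extinction `capsule_mu` and thickness
#' `capsule_thickness` over parenchyma whose extinction `mu_fun(x, y)`
#' may vary laterally), and a set of ellipsoidal inclusions that override
#' the local extinction: low-backscatter tubule lumens (rendered dark) and
#' vessel-like tubes. Intensities are normalized to the unit interval.
#'
#' @param extent numeric length-4 `(xmin, xmax, ymin, ymax)` mm, base frame.
#' @param height_fun function `(x, y)` with scalar `x` and vector `y`
#'   returning surface altitude in base-frame mm.
#' @param mu_fun function `(x, y)` returning parenchyma extinction, mm^-1.
#' @param capsule_mu,capsule_thickness capsule extinction (mm^-1) and
#'   thickness (mm); a thickness of 0 yields a homogeneous medium.
#' @param ellipsoids data frame with columns `cx, cy, cz, ax, ay, az`
#'   (centre and semi-axes, mm), `theta` (azimuth of the first semi-axis
#'   in the horizontal plane, rad; the `az` axis stays vertical), `mu`
#'   (mm^-1), `backscatter` (relative backscatter factor) and `is_lumen`.
#' @param background_level mean intensity above the surface.
#' @param surface_reflectivity intensity of the 1-pixel specular surface line.
#' @param subsurface_peak intensity immediately below the surface (I0).
#' @param rng_seed integer seed recorded with the scene.
#' @param metadata free-form list of ground truth (glyphs, lumen diameters).
#' @param kind character tag.
#' @return An object of class `oct_scene`.
#' @export
synthetic_scene <- function(extent, height_fun,
                            mu_fun = function(x, y) rep(1.0, length(y)),
                            capsule_mu = 0, capsule_thickness = 0,
                            ellipsoids = empty_ellipsoids(),
                            background_level = 0.02,
                            surface_reflectivity = 0.8,
                            subsurface_peak = 0.6,
                            rng_seed = NULL, metadata = list(),
                            kind = "custom") {
  stopifnot(length(extent) == 4L, extent[2] > extent[1], extent[4] > extent[3])
  ellipsoids <- normalize_ellipsoids(ellipsoids)
  if (any(ellipsoids$mu < 0) || capsule_mu < 0)
    stop("attenuation values must be non-negative")
  sc <- structure(list(extent = as.numeric(extent), height_fun = height_fun,
                       mu_fun = mu_fun, capsule_mu = capsule_mu,
                       capsule_thickness = capsule_thickness,
                       ellipsoids = ellipsoids,
                       background_level = background_level,
                       surface_reflectivity = surface_reflectivity,
                       subsurface_peak = subsurface_peak,
                       rng_seed = rng_seed, metadata = metadata, kind = kind),
                  class = "oct_scene")
  if (nrow(ellipsoids)) {
    surf <- vapply(seq_len(nrow(ellipsoids)), function(i)
      scene_height(sc, ellipsoids$cx[i], ellipsoids$cy[i]), numeric(1))
    # inclusions must sit strictly below the surface (vertical clearance)
    if (any(ellipsoids$cz + ellipsoids$az >= surf))
      stop("every ellipsoid must lie strictly below the surface")
  }
  sc
}

#' @export
print.oct_scene <- function(x, ...) {
  cat(sprintf("<oct_scene:%s> footprint %.3g x %.3g mm, %d inclusion(s)\n",
              x$kind, diff(x$extent[1:2]), diff(x$extent[3:4]),
              nrow(x$ellipsoids)))
  invisible(x)
}

#' Surface height of a scene
#'
#' @param scene An `oct_scene`.
#' @param x scalar base-frame x, mm.
#' @param y vector of base-frame y, mm.
#' @return Surface altitude(s), mm.
#' @export
scene_height <- function(scene, x, y) scene$height_fun(x, y)

#' Sample the scene height field on a regular lattice
#'
#' @param scene An `oct_scene`.
#' @param pitch lattice pitch, mm.
#' @return List with `xs`, `ys` and matrix `z` (length(xs) x length(ys)).
#' @export
scene_height_grid <- function(scene, pitch = 0.05) {
  xs <- seq(scene$extent[1], scene$extent[2], by = pitch)
  ys <- seq(scene$extent[3], scene$extent[4], by = pitch)
  z <- t(vapply(xs, function(x) scene_height(scene, x, ys),
                numeric(length(ys))))
  list(xs = xs, ys = ys, z = z)
}

#' Default letter-like glyph set for the accuracy phantom
#'
#' Eight simple stroke-built glyphs (bars and els) laid out on a row, each
#' with a known bounding extent used as ground truth when scoring a
#' reconstructed depth map.
#'
#' @param n_glyphs number of glyphs (at most 8).
#' @param glyph_size numeric length-2 `(dx, dy)` nominal glyph extent, mm.
#' @param spacing centre-to-centre spacing along y, mm.
#' @param origin lower-left corner `(x0, y0)` of the first glyph, mm.
#' @return Glyph list usable as `glyph_spec` in [make_letter_phantom()].
#' @export
phantom_glyphs <- function(n_glyphs = 8, glyph_size = c(4, 2.4),
                           spacing = 3.4, origin = c(2, 1.2)) {
  stopifnot(n_glyphs >= 1, n_glyphs <= 8)
  dx <- glyph_size[1]; dy <- glyph_size[2]
  bar <- 0.8  # stroke width, mm
  shapes <- list(
    I = function(x0, y0) list(c(x0, x0 + dx, y0 + dy/2 - bar/2, y0 + dy/2 + bar/2)),
    L = function(x0, y0) list(c(x0, x0 + dx, y0, y0 + bar),
                              c(x0, x0 + bar, y0, y0 + dy)),
    T = function(x0, y0) list(c(x0 + dx - bar, x0 + dx, y0, y0 + dy),
                              c(x0, x0 + dx, y0 + dy/2 - bar/2, y0 + dy/2 + bar/2)),
    H = function(x0, y0) list(c(x0, x0 + dx, y0, y0 + bar),
                              c(x0, x0 + dx, y0 + dy - bar, y0 + dy),
                              c(x0 + dx/2 - bar/2, x0 + dx/2 + bar/2, y0, y0 + dy)),
    U = function(x0, y0) list(c(x0, x0 + dx, y0, y0 + bar),
                              c(x0, x0 + dx, y0 + dy - bar, y0 + dy),
                              c(x0, x0 + bar, y0, y0 + dy)),
    C = function(x0, y0) list(c(x0, x0 + dx, y0, y0 + bar),
                              c(x0, x0 + dx, y0 + dy - bar, y0 + dy),
                              c(x0 + dx - bar, x0 + dx, y0, y0 + dy)),
    F = function(x0, y0) list(c(x0 + dx - bar, x0 + dx, y0, y0 + dy),
                              c(x0, x0 + dx, y0, y0 + bar),
                              c(x0 + dx/2 - bar/2, x0 + dx/2 + bar/2, y0, y0 + dy)),
    E = function(x0, y0) list(c(x0 + dx - bar, x0 + dx, y0, y0 + dy),
                              c(x0, x0 + bar, y0, y0 + dy),
                              c(x0 + dx/2 - bar/2, x0 + dx/2 + bar/2, y0, y0 + dy))
  )
  nm <- names(shapes)[seq_len(n_glyphs)]
  lapply(seq_len(n_glyphs), function(i) {
    y0 <- origin[2] + (i - 1) * spacing
    list(name = nm[i], strokes = shapes[[nm[i]]](origin[1], y0))
  })
}

#' Letter-extrusion accuracy phantom
#'
#' Builds a flat-base scene with letter-shaped extrusions assembled from
#' axis-aligned rectangular strokes, mimicking a 3D-printed localization
#' phantom. Attenuation is uniform; there are no lumens. Per-glyph ground
#' truth (bounding extent along the elevational x and lateral y axes, and
#' extrusion height) is recorded in the scene metadata.
#'
#' @param footprint numeric length-2 `(size_x, size_y)` mm.
#' @param extrusion_heights heights of the glyph extrusions, mm; recycled
#'   over glyphs. Must be positive.
#' @param glyph_spec list of glyphs, each `list(name, strokes)` with strokes
#'   as `c(xmin, xmax, ymin, ymax)` rectangles (mm). Overlapping strokes
#'   take the maximum height.
#' @param mu uniform extinction coefficient, mm^-1.
#' @param ... passed to [synthetic_scene()].
#' @return An `oct_scene` of kind `"letter_phantom"`.
#' @export
make_letter_phantom <- function(footprint = c(20, 14),
                                extrusion_heights = 0.5,
                                glyph_spec = phantom_glyphs(4, spacing = 3.4),
                                mu = 2.0, ...) {
  stopifnot(all(footprint > 0))
  if (any(extrusion_heights <= 0)) stop("extrusion heights must be positive")
  hts <- rep_len(extrusion_heights, length(glyph_spec))
  glyphs <- lapply(seq_along(glyph_spec), function(i) {
    g <- glyph_spec[[i]]
    # strokes may arrive as a list of length-4 vectors (native) or as a
    # matrix/data frame with one rectangle per row (JSON round trip)
    if (is.matrix(g$strokes) || is.data.frame(g$strokes)) {
      m <- as.matrix(g$strokes)
      g$strokes <- lapply(seq_len(nrow(m)), function(r) as.numeric(m[r, ]))
    }
    bb <- if (length(g$strokes)) {
      s <- do.call(rbind, g$strokes)
      c(min(s[, 1]), max(s[, 2]), min(s[, 3]), max(s[, 4]))
    } else c(NA_real_, NA_real_, NA_real_, NA_real_)
    list(name = g$name, strokes = g$strokes, height = hts[i], bbox = bb,
         extent_x = bb[2] - bb[1], extent_y = bb[4] - bb[3])
  })
  height_fun <- function(x, y) {
    h <- numeric(length(y))
    for (g in glyphs) for (s in g$strokes) {
      if (x >= s[1] && x <= s[2]) {
        inb <- y >= s[3] & y <= s[4]
        if (any(inb)) h[inb] <- pmax(h[inb], g$height)
      }
    }
    h
  }
  mu <- force(mu)
  synthetic_scene(extent = c(0, footprint[1], 0, footprint[2]),
                  height_fun = height_fun,
                  mu_fun = function(x, y) rep(mu, length(y)),
                  metadata = list(glyphs = glyphs),
                  kind = "letter_phantom", ...)
}

#' Kidney-like synthetic scene
#'
#' Emulates the anatomy relevant to large-area renal OCT: a smooth random
#' surface with millimetre-scale relief, a thin higher-attenuation capsule
#' stratum over parenchyma, a few superficial low-attenuation vessel-like
#' tubes, and a population of dark tubule lumens. Lumens are modeled as
#' strongly elongated ellipsoids running along the elevational (x) axis so
#' that their B-scan cross-sections are near-circular with the sampled
#' diameter, as for tubules cut transversally by the scan plane.
#'
#' @param extent numeric length-4 `(xmin, xmax, ymin, ymax)` mm.
#' @param relief_amplitude standard deviation of the surface relief, mm.
#' @param correlation_length lateral correlation length of the relief, mm.
#' @param base_z mean surface altitude in the base frame, mm.
#' @param capsule_mu,capsule_thickness capsule extinction (mm^-1), thickness (mm).
#' @param parenchyma_mu parenchyma extinction, mm^-1; either a scalar or a
#'   function `(x, y)` for laterally varying tissue.
#' @param n_vessels number of superficial vessel-like tubes.
#' @param vessel_mu,vessel_radius vessel extinction (mm^-1) and radius (mm).
#' @param lumen_density lumens per mm^2 of footprint.
#' @param lumen_diameter_mean,lumen_diameter_sd lumen diameter distribution, um.
#' @param lumen_depth_range depth range of lumen centres below the local
#'   surface, mm.
#' @param lumen_mu,lumen_backscatter lumen fill extinction (mm^-1) and
#'   relative backscatter (dark when well below 1).
#' @param seed integer seed; a fixed seed reproduces the scene exactly.
#' @param ... passed to [synthetic_scene()].
#' @return An `oct_scene` of kind `"kidney"`; ground-truth lumen diameters
#'   (um) are stored in `metadata$lumen_diameters_um`.
#' @export
make_kidney_scene <- function(extent = c(0, 2, 0, 2),
                              relief_amplitude = 0.3,
                              correlation_length = 2.0,
                              base_z = 0,
                              capsule_mu = 3.0, capsule_thickness = 0.05,
                              parenchyma_mu = 1.5,
                              n_vessels = 0, vessel_mu = 0.3,
                              vessel_radius = 0.05,
                              lumen_density = 0, lumen_diameter_mean = 40,
                              lumen_diameter_sd = 6,
                              lumen_depth_range = c(0.08, 0.35),
                              lumen_mu = 0.2, lumen_backscatter = 0.05,
                              seed = 1, ...) {
  stopifnot(relief_amplitude >= 0, lumen_density >= 0, correlation_length > 0)
  ext <- as.numeric(extent)
  with_local_seed(seed, {
    # band-limited random relief: white noise on a coarse lattice, Gaussian
    # smoothed to the stated correlation length, rescaled to the amplitude
    pitch <- correlation_length / 4
    nx <- max(8L, ceiling(diff(ext[1:2]) / pitch) + 5L)
    ny <- max(8L, ceiling(diff(ext[3:4]) / pitch) + 5L)
    if (relief_amplitude > 0) {
      z <- matrix(rnorm(nx * ny), nx, ny)
      z <- gauss_smooth(z, sigma = 2)
      z <- base_z + relief_amplitude * (z - mean(z)) / max(sd(z), 1e-12)
    } else {
      z <- matrix(base_z, nx, ny)
    }
    xs <- seq(ext[1] - 2 * pitch, by = pitch, length.out = nx)
    ys <- seq(ext[3] - 2 * pitch, by = pitch, length.out = ny)
    height_fun <- bilinear_grid(xs, ys, z)

    mu_fun <- if (is.function(parenchyma_mu)) parenchyma_mu
              else {pm <- parenchyma_mu; function(x, y) rep(pm, length(y))}

    ell <- empty_ellipsoids()
    if (n_vessels > 0) {
      # superficial tubes running along x across the footprint
      vy <- runif(n_vessels, ext[3], ext[4])
      vdepth <- runif(n_vessels, 0.1, 0.3)
      vz <- vapply(seq_len(n_vessels),
                   function(i) height_fun((ext[1] + ext[2]) / 2, vy[i]),
                   numeric(1)) - vdepth
      ell <- rbind(ell, data.frame(
        cx = (ext[1] + ext[2]) / 2, cy = vy, cz = vz,
        ax = diff(ext[1:2]), ay = vessel_radius, az = vessel_radius,
        theta = 0, mu = vessel_mu, backscatter = 1, is_lumen = FALSE))
    }
    lumen_d <- numeric(0)
    n_lum <- round(lumen_density * diff(ext[1:2]) * diff(ext[3:4]))
    if (n_lum > 0) {
      d_um <- rnorm(n_lum, lumen_diameter_mean, lumen_diameter_sd)
      d_um <- pmax(d_um, 6)
      r_mm <- d_um / 2000
      lx <- runif(n_lum, ext[1], ext[2])
      ly <- runif(n_lum, ext[3] + 0.05, ext[4] - 0.05)
      ldep <- runif(n_lum, lumen_depth_range[1], lumen_depth_range[2])
      lz <- vapply(seq_len(n_lum), function(i) height_fun(lx[i], ly[i]),
                   numeric(1)) - ldep
      # tubule-like: long horizontal axis at a random azimuth, spanning
      # past the footprint so in-extent cross-sections stay close to the
      # nominal diameter; the centerline measurement recovers the true
      # bore regardless of the cut obliquity
      ax <- 2 * sum(abs(diff(ext)[c(1, 3)])) + 1
      ell <- rbind(ell, data.frame(cx = lx, cy = ly, cz = lz,
                                   ax = ax, ay = r_mm, az = r_mm,
                                   theta = runif(n_lum, 0, pi),
                                   mu = lumen_mu,
                                   backscatter = lumen_backscatter,
                                   is_lumen = TRUE))
      lumen_d <- d_um
    }
    synthetic_scene(extent = ext, height_fun = height_fun, mu_fun = mu_fun,
                    capsule_mu = capsule_mu,
                    capsule_thickness = capsule_thickness,
                    ellipsoids = ell, rng_seed = seed,
                    metadata = list(lumen_diameters_um = lumen_d),
                    kind = "kidney", ...)
  })
}
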