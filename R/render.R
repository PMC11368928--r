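#' Render a B-scan from a synthetic scene
#'
#' Simulates the image a spectral-domain OCT probe would acquire at the
#' given pose, using single-scattering image formation: the backscattered
#' intensity a depth d below the surface is `I0 * exp(-2 * M(d))` where
#' `M(d)` is the accumulated extinction integral along the A-scan, with the
#' local extinction taken from the scene's layered model and any ellipsoidal
#' inclusion the ray passes through. Pixels above the surface carry the
#' background level, the surface itself a 1-pixel specular line, and lumen
#' interiors a reduced backscatter factor (dark). Optional multiplicative
#' log-normal speckle (mean 1) is applied to the whole image. Intensities
#' are clipped to [0, 1].
#'
#' @param scene An `oct_scene`.
#' @param pose An `oct_pose` with the scanning orientation `diag(1,-1,-1)`
#'   (the probe looking straight down); scanline motion is pure translation.
#' @param geom A `pixel_geometry`.
#' @param speckle_sd standard deviation of log-intensity speckle; 0 disables.
#' @param seed optional integer seed making the speckle reproducible.
#' @return An object of class `oct_bscan`: list with `image` (n_axial x
#'   n_lateral matrix, rows = axial), `pose`, and `geom`.
#' @export
render_bscan <- function(scene, pose, geom, speckle_sd = 0, seed = NULL) {
  if (max(abs(pose$rotation - diag(c(1, -1, -1)))) > 1e-9)
    stop("render_bscan requires the scanning orientation diag(1,-1,-1)")
  nr <- geom$n_axial; nc <- geom$n_lateral
  x <- pose$translation[1]
  cols <- seq_len(nc) - 1
  # probe y maps to -y of base under the scanning orientation
  ybase <- pose$translation[2] - (cols - (nc - 1) / 2) * geom$res_lateral
  z0 <- pose$translation[3]

  h <- scene_height(scene, x, ybase)
  rs <- (z0 - h) / geom$res_axial          # fractional surface row per column
  if (any(rs < 0))
    stop("collision: probe aperture is below the sample surface")

  img <- matrix(scene$background_level, nr, nc)
  if (all(rs >= nr)) {                      # sample entirely out of axial FOV
    img <- apply_speckle(img, speckle_sd, seed)
    return(new_bscan(img, pose, geom))
  }

  rows <- 0:(nr - 1)
  D <- outer(rows, rs, "-") * geom$res_axial      # depth below surface, mm
  r0 <- floor(rs + 0.5)                           # surface pixel row
  rowmat <- matrix(rows, nr, nc)
  r0mat <- matrix(r0, nr, nc, byrow = TRUE)
  below <- rowmat > r0mat

  # accumulated extinction integral of the layered model
  tc <- scene$capsule_thickness
  mu_par <- scene$mu_fun(x, ybase)
  M <- scene$capsule_mu * pmin(D, tc) +
       sweep(pmax(D - tc, 0), 2L, mu_par, "*")
  bs <- matrix(1, nr, nc)

  ell <- scene$ellipsoids
  if (nrow(ell)) {
    # layered extinction at a given depth (for the inclusion differential)
    mu_at <- function(dep, j) ifelse(dep < tc, scene$capsule_mu, mu_par[j])
    for (k in seq_len(nrow(ell))) {
      # rotate the horizontal offsets into the ellipsoid frame (the
      # vertical semi-axis az is unaffected by the azimuth)
      th <- if (is.null(ell$theta)) 0 else ell$theta[k]
      dxx <- x - ell$cx[k]; dyy <- ybase - ell$cy[k]
      u <- cos(th) * dxx + sin(th) * dyy
      v <- -sin(th) * dxx + cos(th) * dyy
      q <- (u / ell$ax[k])^2 + (v / ell$ay[k])^2
      js <- which(q < 1)
      if (!length(js)) next
      s <- ell$az[k] * sqrt(1 - q[js])
      d1 <- (h[js] - (ell$cz[k] + s))      # entry depth
      d2 <- (h[js] - (ell$cz[k] - s))      # exit depth
      dmid <- (d1 + d2) / 2
      dmu <- ell$mu[k] - mu_at(dmid, js)
      Dj <- D[, js, drop = FALSE]
      d1m <- matrix(d1, nr, length(js), byrow = TRUE)
      d2m <- matrix(d2, nr, length(js), byrow = TRUE)
      len <- pmin(pmax(Dj - d1m, 0), d2m - d1m)
      M[, js] <- M[, js] + len * matrix(dmu, nr, length(js), byrow = TRUE)
      inside <- Dj > d1m & Dj < d2m
      if (ell$backscatter[k] != 1) {
        bsj <- bs[, js, drop = FALSE]
        bsj[inside] <- ell$backscatter[k]
        bs[, js] <- bsj
      }
    }
  }

  sub <- below & D > 0
  img[sub] <- scene$subsurface_peak * bs[sub] * exp(-2 * M[sub])
  surfpix <- rowmat == r0mat & r0mat <= nr - 1 & r0mat >= 0
  img[surfpix] <- scene$surface_reflectivity

  img <- apply_speckle(img, speckle_sd, seed)
  new_bscan(img, pose, geom)
}

apply_speckle <- function(img, speckle_sd, seed) {
  if (speckle_sd <= 0) return(pmin(pmax(img, 0), 1))
  with_local_seed(seed, {
    # log-normal, unit mean: exp(N(-sd^2/2, sd))
    noise <- exp(rnorm(length(img), -speckle_sd^2 / 2, speckle_sd))
    pmin(pmax(img * noise, 0), 1)
  })
}

new_bscan <- function(image, pose, geom) {
  structure(list(image = image, pose = pose, geom = geom),
            class = "oct_bscan")
}

#' @export
print.oct_bscan <- function(x, ...) {
  cat(sprintf("<oct_bscan> %d x %d px at t = %.3f s\n",
              nrow(x$image), ncol(x$image), x$pose$timestamp))
  invisible(x)
}
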