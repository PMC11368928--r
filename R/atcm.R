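#' Fit the extinction coefficient of one A-scan
#'
#' Fits the single-scattering decay `I(z) ~ exp(-2 * mu_t * z)` by linear
#' least squares on log-intensity over a depth window just below the
#' detected surface, skipping `offset_rows` pixels (the specular surface
#' line) first. Intensities at or below `floor_eps` are excluded; the fit
#' is invalid (`NA`) when fewer than `min_samples` usable samples remain
#' or the surface row itself is invalid.
#'
#' @param a_scan numeric vector of intensities along depth (one B-scan
#'   column, index 1 at the top).
#' @param surface_row 0-based axial index of the surface pixel, or `NA`.
#' @param geom A `pixel_geometry` (supplies the axial pitch).
#' @param window_mm depth window below the surface used for the fit, mm.
#' @param offset_rows pixels skipped below the surface before the window.
#' @param floor_eps intensity floor; samples at or below it are excluded.
#' @param min_samples minimum usable samples for a valid fit.
#' @return Fitted `mu_t` in mm^-1, or `NA_real_` when invalid.
#' @export
fit_extinction <- function(a_scan, surface_row, geom, window_mm = 1.0,
                           offset_rows = 5L, floor_eps = 1e-6,
                           min_samples = 10L) {
  if (is.na(surface_row)) return(NA_real_)
  n <- length(a_scan)
  wrows <- max(2L, round(window_mm / geom$res_axial))
  r0 <- surface_row + offset_rows            # 0-based first fit row
  rows <- r0:(r0 + wrows - 1L)
  rows <- rows[rows < n]
  if (length(rows) < min_samples) return(NA_real_)
  I <- a_scan[rows + 1L]
  use <- is.finite(I) & I > floor_eps
  if (sum(use) < min_samples) return(NA_real_)
  x <- rows[use] * geom$res_axial
  y <- log(I[use])
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  if (!is.finite(slope)) return(NA_real_)
  max(-slope / 2, 0)
}

# Vectorized per-frame extinction fit: one slope per column with in-window,
# above-floor masking. Returns a numeric vector (NA where invalid).
fit_extinction_frame <- function(img, surface_rows, geom, window_mm = 1.0,
                                 offset_rows = 5L, floor_eps = 1e-6,
                                 min_samples = 10L) {
  nr <- nrow(img); nc <- ncol(img)
  wrows <- max(2L, round(window_mm / geom$res_axial))
  out <- rep(NA_real_, nc)
  ok <- which(!is.na(surface_rows))
  if (!length(ok)) return(out)
  r0 <- surface_rows[ok] + offset_rows
  rel <- 0:(wrows - 1L)
  rowm <- outer(rel, r0, "+")                       # wrows x n_ok, 0-based
  inrange <- rowm < nr
  rowm_c <- pmin(rowm, nr - 1L)
  lin <- rowm_c + 1L + nr * matrix(ok - 1L, wrows, length(ok), byrow = TRUE)
  I <- matrix(img[lin], wrows, length(ok))
  use <- inrange & is.finite(I) & I > floor_eps
  x <- rowm * geom$res_axial
  y <- log(pmax(I, floor_eps))
  x[!use] <- 0; y[!use] <- 0
  n <- colSums(use)
  sx <- colSums(x); sy <- colSums(y)
  sxx <- colSums(x * x); sxy <- colSums(x * y)
  denom <- n * sxx - sx^2
  slope <- (n * sxy - sx * sy) / denom
  mu <- pmax(-slope / 2, 0)
  mu[n < min_samples | !is.finite(mu)] <- NA_real_
  out[ok] <- mu
  out
}

#' Axial-attenuation map (ATCM) of one scanline
#'
#' Parameterizes every A-scan of a tracked scan by its fitted extinction
#' coefficient and arranges the values on the (elevational, lateral) grid
#' placed by the recorded poses. Columns of the B-scan are reordered so
#' that the map's lateral axis ascends in base-frame y.
#'
#' @param scan A `tracked_scan`.
#' @param window_mm,offset_rows,floor_eps,min_samples see [fit_extinction()].
#' @param lower,upper,m_persist surface-detection parameters.
#' @return A `parameter_map` of kind `"ATCM"` (values in mm^-1).
#' @export
atcm <- function(scan, window_mm = 1.0, offset_rows = 5L, floor_eps = 1e-6,
                 min_samples = 10L, lower = 0.15, upper = 0.85,
                 m_persist = 3L) {
  geom <- scan$geom
  nf <- length(scan$frames)
  nc <- geom$n_lateral
  vals <- matrix(NA_real_, nf, nc)
  for (t in seq_len(nf)) {
    det <- detect_surface(scan$frames[[t]], lower, upper, m_persist)
    vals[t, ] <- fit_extinction_frame(scan$frames[[t]], det$surface_rows,
                                      geom, window_mm, offset_rows,
                                      floor_eps, min_samples)
  }
  tr <- do.call(rbind, lapply(scan$poses, function(p) p$translation))
  pitch_e <- if (nf > 1L) (tr[nf, 1] - tr[1, 1]) / (nf - 1L)
             else if (!is.null(scan$plan)) scan$plan$pitch_elev
             else geom$res_lateral
  # B-scan column c sits at y = t_y - (c - (nc-1)/2) * res_lateral:
  # reverse columns so the lateral axis ascends in base y
  vals <- vals[, nc:1, drop = FALSE]
  y_min <- tr[1, 2] - (nc - 1) / 2 * geom$res_lateral
  parameter_map(vals, is.finite(vals),
                origin_xy = c(tr[1, 1] - pitch_e / 2,
                              y_min - geom$res_lateral / 2),
                pitch_xy = c(pitch_e, geom$res_lateral), kind = "ATCM")
}
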