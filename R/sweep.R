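#' Scan-speed grid
#'
#' Inclusive arithmetic sequence of candidate robot speeds, defaulting to
#' 0.6 to 5.1 mm/s in 0.5 mm/s increments (ten values).
#'
#' @param v0,v1 first and last speed, mm/s (`v1 >= v0`).
#' @param step increment, mm/s.
#' @return Numeric vector of speeds.
#' @export
speed_grid <- function(v0 = 0.6, v1 = 5.1, step = 0.5) {
  if (v1 < v0 || step <= 0) stop("need v1 >= v0 and step > 0")
  v0 + step * (0:floor((v1 - v0) / step + 1e-9))
}

#' Simulate a faster scan by elevational downsampling
#'
#' At a fixed B-scan rate, scanning `v / v_ref` times faster acquires one
#' elevational line per `round(v / v_ref)` of the reference scan. The map
#' keeps every such line and re-expands to the original elevational size
#' by nearest-line replication, so the result stays comparable pixelwise
#' with the original.
#'
#' @param map A `parameter_map` (rows = elevational lines).
#' @param v simulated speed, mm/s (`v >= v_ref`).
#' @param v_ref acquisition speed of the map, mm/s.
#' @return A `parameter_map` of the same shape and kind.
#' @export
simulate_speed <- function(map, v, v_ref) {
  if (v < v_ref) stop("cannot simulate speeds below the acquisition speed")
  interval <- max(1L, as.integer(round(v / v_ref)))
  if (interval == 1L) return(map)
  n <- nrow(map$values)
  kept <- seq(1L, n, by = interval)
  src <- kept[floor((seq_len(n) - 1L) / interval) + 1L]
  parameter_map(map$values[src, , drop = FALSE],
                map$valid[src, , drop = FALSE],
                map$origin_xy, map$pitch_xy, map$kind)
}

# Windowed mean via cumulative sums; returns the (n-w+1) x (m-w+1) matrix
# of w x w box means.
box_mean <- function(M, w) {
  cs <- apply(apply(M, 2L, cumsum), 1L, cumsum)  # transposed cumsum matrix
  cs <- t(cs)
  n <- nrow(M); m <- ncol(M)
  Z <- matrix(0, n + 1L, m + 1L)
  Z[2:(n + 1L), 2:(m + 1L)] <- cs
  i <- 1:(n - w + 1L); j <- 1:(m - w + 1L)
  (Z[i + w, j + w, drop = FALSE] - Z[i, j + w, drop = FALSE] -
     Z[i + w, j, drop = FALSE] + Z[i, j, drop = FALSE]) / (w * w)
}

#' Structural-similarity quality score between two parameter maps
#'
#' Both maps are normalized to [0, 1] by the original's value range, then
#' the mean local structural-similarity index is computed with a square
#' sliding window (local means, variances and covariance with the standard
#' stabilizing constants C1 = 0.01^2, C2 = 0.03^2 on unit dynamic range).
#' Invalid cells enter as 0 after normalization.
#'
#' @param degraded,original `parameter_map`s (or plain matrices) of one
#'   shape.
#' @param window odd window size in cells.
#' @return Score in [0, 1]; 1 for identical maps.
#' @export
quality_score <- function(degraded, original, window = 7L) {
  gm <- function(m) if (inherits(m, "parameter_map")) {
    v <- m$values; v[!m$valid] <- NA_real_; v
  } else m
  A <- gm(degraded); B <- gm(original)
  if (!all(dim(A) == dim(B))) stop("maps must share a shape")
  rng <- range(B, na.rm = TRUE)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  A <- (A - rng[1]) / scale
  B <- (B - rng[1]) / scale
  A[!is.finite(A)] <- 0
  B[!is.finite(B)] <- 0
  w <- min(window, dim(A))
  C1 <- 0.01^2; C2 <- 0.03^2
  mu1 <- box_mean(A, w); mu2 <- box_mean(B, w)
  s11 <- box_mean(A * A, w) - mu1^2
  s22 <- box_mean(B * B, w) - mu2^2
  s12 <- box_mean(A * B, w) - mu1 * mu2
  ssim <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  mean(ssim)
}

#' Theoretical scan time at a different speed
#'
#' Scan time scales inversely with speed at a fixed trajectory:
#' `t_ref * v_ref / v`, truncated to whole seconds.
#'
#' @param t_ref reference scan duration, s.
#' @param v_ref reference speed, mm/s.
#' @param v target speed, mm/s.
#' @return Whole seconds.
#' @export
theoretical_scan_time <- function(t_ref, v_ref, v) {
  if (any(c(t_ref, v_ref, v) <= 0)) stop("all arguments must be positive")
  floor(t_ref * v_ref / v)
}

#' Expected B-scan count at a different speed
#'
#' At a fixed acquisition rate the number of B-scans over the same
#' trajectory is `floor(n_ref * v_ref / v)`.
#'
#' @param n_ref frame count at the reference speed.
#' @param v_ref reference speed, mm/s.
#' @param v target speed, mm/s.
#' @return Whole frames.
#' @export
expected_frame_count <- function(n_ref, v_ref, v) {
  if (any(c(n_ref, v_ref, v) <= 0)) stop("all arguments must be positive")
  floor(n_ref * v_ref / v)
}

#' Speed sweep of a parameter map
#'
#' Degrades the map at every speed of the grid via [simulate_speed()] and
#' scores each degraded map against the original with [quality_score()].
#'
#' @param map A `parameter_map` acquired at `v_ref`.
#' @param v_ref acquisition speed, mm/s.
#' @param speeds speed grid, mm/s; defaults to [speed_grid()].
#' @param window SSIM window.
#' @return Data frame with `speed`, `interval`, `quality`.
#' @export
speed_sweep <- function(map, v_ref = 0.6, speeds = speed_grid(),
                        window = 7L) {
  data.frame(
    speed = speeds,
    interval = vapply(speeds, function(v) max(1L, as.integer(round(v / v_ref))),
                      integer(1)),
    quality = vapply(speeds, function(v)
      quality_score(simulate_speed(map, v, v_ref), map, window), numeric(1)))
}
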