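#' Construct a probe pose
#'
#' A pose is the rigid transform from the OCT probe frame to the robot base
#' frame: a 3x3 rotation, a translation in millimetres, and a timestamp in
#' seconds. The probe frame originates at the top centre of the B-scan with
#' x pointing along the elevational (scan) direction, y along the B-scan
#' lateral axis, and z along the axial axis into the tissue.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation numeric length-3, mm in the base frame.
#' @param timestamp seconds; monotone within a scan.
#' @return An object of class `oct_pose`.
#' @export
pose <- function(rotation = diag(3), translation = c(0, 0, 0), timestamp = 0) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    stop("pose requires a 3x3 rotation and a length-3 translation")
  check_rotation(rotation)
  structure(list(rotation = rotation, translation = translation,
                 timestamp = as.numeric(timestamp)),
            class = "oct_pose")
}

check_rotation <- function(R, tol = 1e-9) {
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol)
    stop("rotation must be orthonormal with determinant +1")
  invisible(R)
}

#' @export
print.oct_pose <- function(x, ...) {
  cat(sprintf("<oct_pose> t = %.4f s, translation = (%.3f, %.3f, %.3f) mm\n",
              x$timestamp, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Compose two poses
#'
#' Returns the pose equivalent to applying `b` first and then `a`
#' (matrix product of the homogeneous transforms).
#'
#' @param a,b `oct_pose` objects.
#' @return An `oct_pose` with the timestamp of `a`.
#' @export
pose_compose <- function(a, b) {
  pose(a$rotation %*% b$rotation,
       as.numeric(a$rotation %*% b$translation) + a$translation,
       a$timestamp)
}

#' Invert a pose
#'
#' @param p An `oct_pose`.
#' @return The inverse transform as an `oct_pose` with the same timestamp.
#' @export
pose_inverse <- function(p) {
  Rt <- t(p$rotation)
  pose(Rt, as.numeric(-Rt %*% p$translation), p$timestamp)
}

#' Pose as a 4x4 homogeneous matrix
#' @param p An `oct_pose`.
#' @return 4x4 numeric matrix.
#' @export
pose_matrix <- function(p) {
  m <- diag(4)
  m[1:3, 1:3] <- p$rotation
  m[1:3, 4] <- p$translation
  m
}

#' B-scan pixel geometry
#'
#' Pixel resolutions and raster size of a B-scan. Defaults are the system
#' configuration used throughout: 2.73 um per lateral pixel, 2.68 um per
#' axial pixel, 1800 x 700 pixels. Values are stored in mm per pixel.
#'
#' @param res_lateral mm per lateral pixel.
#' @param res_axial mm per axial pixel.
#' @param n_lateral number of lateral pixels (B-scan columns).
#' @param n_axial number of axial pixels (B-scan rows).
#' @return An object of class `pixel_geometry` with derived fields
#'   `fov_lateral` (W_OCT, mm) and `fov_axial_mm` (mm).
#' @export
pixel_geometry <- function(res_lateral = 2.73e-3, res_axial = 2.68e-3,
                           n_lateral = 1800L, n_axial = 700L) {
  if (any(c(res_lateral, res_axial, n_lateral, n_axial) <= 0))
    stop("all pixel geometry fields must be strictly positive")
  structure(list(res_lateral = res_lateral, res_axial = res_axial,
                 n_lateral = as.integer(n_lateral),
                 n_axial = as.integer(n_axial),
                 fov_lateral = n_lateral * res_lateral,
                 fov_axial_mm = n_axial * res_axial),
            class = "pixel_geometry")
}

#' @export
print.pixel_geometry <- function(x, ...) {
  cat(sprintf("<pixel_geometry> %d x %d px (lateral x axial), %.3g x %.3g mm FOV\n",
              x$n_lateral, x$n_axial, x$fov_lateral, x$fov_axial_mm))
  invisible(x)
}

#' Map B-scan pixel indices to probe-frame coordinates
#'
#' Pixel (row, col) maps to `(0, (col - (n_lateral-1)/2) * res_lateral,
#' row * res_axial)` mm: the frame origin sits at the top centre of the
#' B-scan and the scan plane has no elevational extent. Indices are 0-based
#' and address pixel centres; both arguments vectorize.
#'
#' @param row axial pixel index (0-based), scalar or vector.
#' @param col lateral pixel index (0-based), scalar or vector.
#' @param geom A `pixel_geometry`.
#' @return A numeric length-3 vector for scalar input, otherwise a 3-column
#'   matrix (x, y, z) in mm.
#' @export
pixel_to_probe <- function(row, col, geom) {
  if (any(row < 0 | row >= geom$n_axial))
    stop("axial index out of range [0, n_axial)")
  if (any(col < 0 | col >= geom$n_lateral))
    stop("lateral index out of range [0, n_lateral)")
  y <- (col - (geom$n_lateral - 1) / 2) * geom$res_lateral
  z <- row * geom$res_axial
  if (length(row) == 1L && length(col) == 1L) return(c(0, y, z))
  cbind(x = 0, y = y, z = z)
}

#' Transform probe-frame points to the base frame
#'
#' Applies `rotation %*% p + translation`, the homogeneous pixel-to-base
#' mapping used when localizing tracked B-scans.
#'
#' @param p_probe length-3 vector or n x 3 matrix of probe-frame points, mm.
#' @param pose An `oct_pose`.
#' @return Same shape as `p_probe`, in base-frame mm.
#' @export
probe_to_base <- function(p_probe, pose) {
  check_rotation(pose$rotation)
  if (is.matrix(p_probe)) {
    sweep(p_probe %*% t(pose$rotation), 2L, pose$translation, "+")
  } else {
    as.numeric(pose$rotation %*% p_probe) + pose$translation
  }
}

#' Read a pose log CSV
#'
#' The pose log has one row per B-scan frame with columns `timestamp_s`,
#' `r00..r22` (row-major rotation) and `tx_mm, ty_mm, tz_mm`.
#'
#' @param path CSV file path.
#' @return List of `oct_pose`.
#' @export
read_pose_log <- function(path) {
  df <- read.csv(path)
  need <- c("timestamp_s", paste0("r", outer(0:2, 0:2, paste0)),
            "tx_mm", "ty_mm", "tz_mm")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("pose log is missing columns: ", paste(missing, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    R <- matrix(unlist(df[i, paste0("r", c("00","01","02","10","11","12","20","21","22"))]),
                3, 3, byrow = TRUE)
    tryCatch(
      pose(R, unlist(df[i, c("tx_mm", "ty_mm", "tz_mm")]), df$timestamp_s[i]),
      error = function(e) stop("malformed pose at line ", i + 1L, ": ",
                               conditionMessage(e)))
  })
}

#' Write a pose log CSV
#'
#' @param poses list of `oct_pose`.
#' @param path output CSV file path.
#' @return `path`, invisibly.
#' @export
write_pose_log <- function(poses, path) {
  rows <- lapply(poses, function(p) {
    R <- t(p$rotation)  # row-major flatten
    c(timestamp_s = p$timestamp, setNames(as.numeric(R),
      paste0("r", c("00","01","02","10","11","12","20","21","22"))),
      tx_mm = p$translation[1], ty_mm = p$translation[2], tz_mm = p$translation[3])
  })
  df <- as.data.frame(do.call(rbind, rows))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
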