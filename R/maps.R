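#' Construct a 2D parameter map
#'
#' A parameter map is a top-view grid in the base-frame x-y plane: rows
#' index the elevational (x) axis and columns the lateral (y) axis. Cell
#' (i, j) is centred at `origin_xy + (c(i, j) - 0.5) * pitch_xy`.
#'
#' @param values numeric matrix (elevational x lateral).
#' @param valid logical matrix of the same shape.
#' @param origin_xy numeric length-2, mm: the low corner of cell (1, 1).
#' @param pitch_xy numeric length-2, mm per cell (elevational, lateral).
#' @param kind one of `"DEPM"`, `"ATCM"`, `"DIAM"` (or a custom tag).
#' @return An object of class `parameter_map`.
#' @export
parameter_map <- function(values, valid = is.finite(values), origin_xy,
                          pitch_xy, kind) {
  if (any(pitch_xy <= 0)) stop("pitch must be positive")
  if (!all(dim(values) == dim(valid))) stop("values/valid shape mismatch")
  if (any(!is.finite(values[valid])))
    stop("values must be finite wherever valid")
  structure(list(values = values, valid = valid,
                 origin_xy = as.numeric(origin_xy),
                 pitch_xy = as.numeric(pitch_xy), kind = kind),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  cat(sprintf("<parameter_map:%s> %d x %d cells of (%.3g, %.3g) mm, %.1f%% valid\n",
              x$kind, nrow(x$values), ncol(x$values), x$pitch_xy[1],
              x$pitch_xy[2], 100 * mean(x$valid)))
  invisible(x)
}

#' Depth-encoded map (DEPM) of a tissue volume
#'
#' For every (x, y) voxel column the surface is the topmost voxel whose
#' mean intensity lies in the detection band and that starts a downward
#' run of at least `m_persist` in-band voxels (the same rule as
#' [detect_surface()]). The map value is the base-frame altitude of that
#' voxel's centre; columns with no such voxel are invalid.
#'
#' @param volume A `tissue_volume`.
#' @param lower,upper intensity band.
#' @param m_persist minimum run of in-band voxels going down.
#' @return A `parameter_map` of kind `"DEPM"` (values in mm).
#' @export
depm <- function(volume, lower = 0.15, upper = 0.95, m_persist = 3L) {
  V <- volume_values(volume)
  d <- dim(V)
  if (prod(d) == 0) stop("empty volume")
  nz <- d[3]
  inb <- V >= lower & V <= upper & volume$counts > 0L
  # reverse z so index 1 is the top, then require a downward in-band run
  inb <- inb[, , nz:1, drop = FALSE]
  cond <- inb
  if (m_persist > 1L && nz > 1L) {
    for (s in seq_len(min(m_persist - 1L, nz - 1L))) {
      shifted <- inb[, , c((s + 1L):nz, rep(nz, s)), drop = FALSE]
      shifted[, , (nz - s + 1L):nz] <- FALSE
      cond <- cond & shifted
    }
  }
  cm <- cond
  dim(cm) <- c(d[1] * d[2], nz)
  has <- rowSums(cm) > 0L
  k_rev <- max.col(cm, ties.method = "first")   # first TRUE along depth
  k <- nz - k_rev + 1L                          # back to ascending-z index
  zval <- volume$origin[3] + (k - 0.5) * volume$voxel_size[3]
  zval[!has] <- NA_real_
  values <- matrix(zval, d[1], d[2])
  parameter_map(values, matrix(has, d[1], d[2]),
                origin_xy = volume$origin[1:2],
                pitch_xy = volume$voxel_size[1:2], kind = "DEPM")
}

#' Score a letter-phantom DEPM against the scene ground truth
#'
#' Reproduces the caliper-style protocol for localization accuracy: per
#' glyph, the extrusion footprint is thresholded out of the DEPM at half
#' the extrusion height and its bounding extent along the elevational
#' (glyph "height") and lateral (glyph "width") axes is compared with the
#' programmed stroke geometry. Absolute errors are reported per glyph and
#' as mean +/- SD per axis. Glyphs with no above-threshold cells are
#' reported as missing.
#'
#' @param map A DEPM `parameter_map`.
#' @param scene The `oct_scene` of kind `"letter_phantom"` that was scanned.
#' @param base_z altitude of the phantom base plane, mm.
#' @param pad search margin around each glyph's bounding box, mm.
#' @return List with `per_glyph` (data frame: name, truth/measured extents,
#'   absolute errors, missing flag) and `summary` (mean and SD of the
#'   height- and width-axis errors, mm).
#' @export
evaluate_depm_accuracy <- function(map, scene, base_z = 0, pad = 1.0) {
  glyphs <- scene$metadata$glyphs
  if (is.null(glyphs)) stop("scene has no glyph ground truth")
  xs <- map$origin_xy[1] + (seq_len(nrow(map$values)) - 0.5) * map$pitch_xy[1]
  ys <- map$origin_xy[2] + (seq_len(ncol(map$values)) - 0.5) * map$pitch_xy[2]
  rows <- lapply(glyphs, function(g) {
    thr <- base_z + g$height / 2
    ir <- which(xs >= g$bbox[1] - pad & xs <= g$bbox[2] + pad)
    jr <- which(ys >= g$bbox[3] - pad & ys <= g$bbox[4] + pad)
    sub <- map$values[ir, jr, drop = FALSE]
    hit <- which(sub > thr & map$valid[ir, jr, drop = FALSE], arr.ind = TRUE)
    if (!nrow(hit))
      return(data.frame(name = g$name, truth_x = g$extent_x,
                        truth_y = g$extent_y, meas_x = NA_real_,
                        meas_y = NA_real_, err_x = NA_real_,
                        err_y = NA_real_, missing = TRUE))
    meas_x <- diff(range(hit[, 1]) + c(0, 1)) * map$pitch_xy[1]
    meas_y <- diff(range(hit[, 2]) + c(0, 1)) * map$pitch_xy[2]
    data.frame(name = g$name, truth_x = g$extent_x, truth_y = g$extent_y,
               meas_x = meas_x, meas_y = meas_y,
               err_x = abs(meas_x - g$extent_x),
               err_y = abs(meas_y - g$extent_y), missing = FALSE)
  })
  per <- do.call(rbind, rows)
  list(per_glyph = per,
       summary = c(height_mean = mean(per$err_x, na.rm = TRUE),
                   height_sd = sd(per$err_x, na.rm = TRUE),
                   width_mean = mean(per$err_y, na.rm = TRUE),
                   width_sd = sd(per$err_y, na.rm = TRUE)))
}

#' Stitch per-scanline parameter maps into one large-area map
#'
#' Maps are placed on a shared grid by their origins; where several lines
#' provide a valid value the results are averaged, giving a smooth
#' transition across the overlapped area. Validity is the union.
#'
#' @param maps list of `parameter_map` of a common kind and pitch.
#' @return The stitched `parameter_map`.
#' @export
stitch_maps <- function(maps) {
  if (inherits(maps, "parameter_map")) maps <- list(maps)
  kinds <- unique(vapply(maps, function(m) m$kind, character(1)))
  if (length(kinds) != 1L) stop("maps must share a kind")
  pit <- do.call(rbind, lapply(maps, function(m) m$pitch_xy))
  if (max(apply(pit, 2L, function(v) diff(range(v)))) > 1e-9)
    stop("maps must share a pitch")
  pitch <- maps[[1]]$pitch_xy
  orig <- do.call(rbind, lapply(maps, function(m) m$origin_xy))
  g0 <- apply(orig, 2L, min)
  # origins are snapped to the shared grid (placement error <= pitch/2);
  # adjacent scanlines are not, in general, an integer number of map
  # cells apart
  offs <- lapply(maps, function(m)
    as.integer(round((m$origin_xy - g0) / pitch)))
  dims <- c(0L, 0L)
  for (i in seq_along(maps))
    dims <- pmax(dims, offs[[i]] + dim(maps[[i]]$values))
  s <- matrix(0, dims[1], dims[2]); n <- matrix(0L, dims[1], dims[2])
  for (i in seq_along(maps)) {
    m <- maps[[i]]; o <- offs[[i]]
    ir <- o[1] + seq_len(nrow(m$values)); jr <- o[2] + seq_len(ncol(m$values))
    v <- m$values; v[!m$valid] <- 0
    s[ir, jr] <- s[ir, jr] + v
    n[ir, jr] <- n[ir, jr] + m$valid
  }
  vals <- matrix(NA_real_, dims[1], dims[2])
  vals[n > 0L] <- s[n > 0L] / n[n > 0L]
  parameter_map(vals, n > 0L, origin_xy = g0, pitch_xy = pitch,
                kind = kinds)
}
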