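#' Map every pixel of a tracked scan into the base frame
#'
#' Composes the pixel-to-probe mapping with each frame's recorded pose,
#' yielding one `(x, y, z, intensity)` sample per pixel. Frames without a
#' pose are skipped with a warning.
#'
#' @param scan A `tracked_scan` (or list with `frames`, `poses`, `geom`).
#' @param frames optional integer subset of frames to emit.
#' @return A data frame with columns `x, y, z` (base-frame mm) and
#'   `intensity`.
#' @export
pixels_to_base <- function(scan, frames = NULL) {
  geom <- scan$geom
  if (is.null(frames)) frames <- seq_along(scan$frames)
  nr <- geom$n_axial; nc <- geom$n_lateral
  yp <- (seq_len(nc) - 1 - (nc - 1) / 2) * geom$res_lateral
  zp <- (seq_len(nr) - 1) * geom$res_axial
  out <- vector("list", length(frames))
  j <- 0L
  for (f in frames) {
    p <- scan$poses[[f]]
    if (is.null(p)) {
      warning("frame ", f, " has no pose; skipped")
      next
    }
    img <- scan$frames[[f]]
    R <- p$rotation; tr <- p$translation
    # p_probe has no x extent: base = yp * R[,2] + zp * R[,3] + t
    X <- outer(zp * R[1, 3], yp * R[1, 2], "+") + tr[1]
    Y <- outer(zp * R[2, 3], yp * R[2, 2], "+") + tr[2]
    Z <- outer(zp * R[3, 3], yp * R[3, 2], "+") + tr[3]
    j <- j + 1L
    out[[j]] <- data.frame(x = as.vector(X), y = as.vector(Y),
                           z = as.vector(Z), intensity = as.vector(img))
  }
  do.call(rbind, out[seq_len(j)])
}

#' Voxelize a point stream into a tissue volume
#'
#' Half-open binning: a point falls into voxel
#' `floor((p - origin) / voxel_size)` componentwise, so a point exactly on
#' a boundary belongs to the higher-index voxel. A voxel's value is the
#' mean of its contributing intensities; contribution counts are retained
#' so further streams can be pooled exactly. Points outside a pre-sized
#' grid expand it (with a message), they are never dropped.
#'
#' @param points data frame with `x, y, z, intensity`.
#' @param voxel_size numeric length-3 `(x, y, z)` voxel edge, mm.
#' @param origin numeric length-3 corner of voxel (0,0,0); defaults to the
#'   componentwise minimum of the points.
#' @param dims optional integer length-3 grid size.
#' @return An object of class `tissue_volume`: `values` and `counts`
#'   (3D arrays indexed x, y, z), `sums`, `origin`, `voxel_size`.
#' @export
voxelize <- function(points, voxel_size, origin = NULL, dims = NULL) {
  if (any(voxel_size <= 0)) stop("voxel_size must be positive")
  pm <- cbind(points$x, points$y, points$z)
  if (is.null(origin)) origin <- apply(pm, 2L, min)
  idx <- floor(sweep(sweep(pm, 2L, origin), 2L, voxel_size, "/"))
  if (any(idx < 0)) {
    message("voxel grid expanded below the stated origin")
    shift <- pmin(apply(idx, 2L, min), 0)
    origin <- origin + shift * voxel_size
    idx <- sweep(idx, 2L, shift)
  }
  need <- apply(idx, 2L, max) + 1L
  if (is.null(dims)) dims <- need
  else if (any(need > dims)) {
    message("voxel grid expanded beyond the stated dims")
    dims <- pmax(dims, need)
  }
  dims <- as.integer(dims)
  vol <- new_tissue_volume(dims, origin, voxel_size)
  accumulate_voxels(vol, idx, points$intensity)
}

new_tissue_volume <- function(dims, origin, voxel_size) {
  structure(list(sums = array(0, dims), counts = array(0L, dims),
                 values = NULL, origin = as.numeric(origin),
                 voxel_size = as.numeric(voxel_size)),
            class = "tissue_volume")
}

accumulate_voxels <- function(vol, idx, intensity) {
  dims <- dim(vol$sums)
  lin <- 1 + idx[, 1] + dims[1] * (idx[, 2] + dims[2] * idx[, 3])
  agg <- rowsum(cbind(intensity, 1), lin)
  at <- as.numeric(rownames(agg))
  vol$sums[at] <- vol$sums[at] + agg[, 1]
  vol$counts[at] <- vol$counts[at] + agg[, 2]
  vol$values <- NULL
  vol
}

#' @export
print.tissue_volume <- function(x, ...) {
  d <- dim(x$sums)
  cat(sprintf("<tissue_volume> %d x %d x %d voxels of (%.3g, %.3g, %.3g) mm, %.1f%% filled\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3], 100 * mean(x$counts > 0)))
  invisible(x)
}

#' Mean-intensity array of a tissue volume
#'
#' @param vol A `tissue_volume`.
#' @return 3D array of mean intensities (0 where no pixel contributed).
#' @export
volume_values <- function(vol) {
  if (!is.null(vol$values)) return(vol$values)
  v <- vol$sums
  nz <- vol$counts > 0L
  v[nz] <- v[nz] / vol$counts[nz]
  v
}

#' Voxelize a tracked scan (or several) frame-by-frame
#'
#' Streams frames through [pixels_to_base()] in chunks so large scans never
#' materialize the full point cloud, pooling contributions exactly as
#' [voxelize()] does. Multiple scans (adjacent scanlines) accumulate into
#' one volume; overlapping contributions are averaged.
#'
#' @param scans a `tracked_scan` or list of them.
#' @param voxel_size numeric length-3, mm; defaults to
#'   `(v_x / frame_rate, res_lateral, res_axial)` of the first scan.
#' @param origin,dims optional grid placement (computed from the pose
#'   extremes when omitted).
#' @param chunk frames per accumulation chunk.
#' @return A `tissue_volume`.
#' @export
voxelize_scan <- function(scans, voxel_size = NULL, origin = NULL,
                          dims = NULL, chunk = 40L) {
  if (inherits(scans, "tracked_scan")) scans <- list(scans)
  geom <- scans[[1]]$geom
  if (is.null(voxel_size)) {
    plan <- scans[[1]]$plan
    pe <- if (!is.null(plan)) {
      plan$pitch_elev
    } else {
      # scans read back from disk carry no plan: infer the elevational
      # pitch from the recorded pose spacing
      xs <- vapply(scans[[1]]$poses, function(p) p$translation[1], numeric(1))
      if (length(xs) > 1L && median(abs(diff(xs))) > 0)
        median(abs(diff(xs))) else geom$res_lateral
    }
    voxel_size <- c(pe, geom$res_lateral, geom$res_axial)
  }
  if (is.null(origin) || is.null(dims)) {
    tr <- do.call(rbind, lapply(scans, function(s)
      do.call(rbind, lapply(s$poses, function(p) p$translation))))
    half_w <- (geom$n_lateral - 1) / 2 * geom$res_lateral
    lo <- c(min(tr[, 1]), min(tr[, 2]) - half_w,
            min(tr[, 3]) - (geom$n_axial - 1) * geom$res_axial)
    hi <- c(max(tr[, 1]), max(tr[, 2]) + half_w, max(tr[, 3]))
    if (is.null(origin)) origin <- lo - 0.5 * voxel_size
    if (is.null(dims)) dims <- floor((hi - origin) / voxel_size) + 1L
  }
  vol <- new_tissue_volume(as.integer(dims), origin, voxel_size)
  for (s in scans) {
    nf <- length(s$frames)
    for (start in seq(1L, nf, by = chunk)) {
      fr <- start:min(start + chunk - 1L, nf)
      pts <- pixels_to_base(s, frames = fr)
      idx <- floor(cbind((pts$x - origin[1]) / voxel_size[1],
                         (pts$y - origin[2]) / voxel_size[2],
                         (pts$z - origin[3]) / voxel_size[3]))
      if (any(idx < 0) || any(sweep(idx, 2L, dim(vol$sums), ">="))) {
        # out-of-grid points expand the grid; they are never dropped
        message("voxel grid expanded during streaming accumulation")
        vol <- expand_volume(vol, pmin(apply(idx, 2L, min), 0),
                             pmax(apply(idx, 2L, max) + 1L, dim(vol$sums)))
        origin <- vol$origin
        idx <- floor(cbind((pts$x - origin[1]) / voxel_size[1],
                           (pts$y - origin[2]) / voxel_size[2],
                           (pts$z - origin[3]) / voxel_size[3]))
      }
      vol <- accumulate_voxels(vol, idx, pts$intensity)
    }
  }
  vol
}

# Grow a volume so that (0-based) indices [shift_lo, need_hi) fit, copying
# existing sums and counts into place.
expand_volume <- function(vol, shift_lo, need_hi) {
  old_dims <- dim(vol$sums)
  shift <- as.integer(-pmin(shift_lo, 0))
  new_dims <- as.integer(pmax(need_hi + shift, old_dims + shift))
  out <- new_tissue_volume(new_dims,
                           vol$origin - shift * vol$voxel_size,
                           vol$voxel_size)
  ix <- shift[1] + seq_len(old_dims[1])
  iy <- shift[2] + seq_len(old_dims[2])
  iz <- shift[3] + seq_len(old_dims[3])
  out$sums[ix, iy, iz] <- vol$sums
  out$counts[ix, iy, iz] <- vol$counts
  out
}
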