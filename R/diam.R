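#' @importFrom EBImage bwlabel distmap
NULL

#' Classical lumen segmentation of one volume slice
#'
#' Default segmenter behind the pluggable lumen-segmentation interface.
#' The slice (axial rows x lateral columns, like a B-scan) is aligned by
#' its detected surface; the median intensity at each depth below the
#' surface estimates the expected single-scattering decay, and pixels far
#' darker than that expectation (ratio below `ratio`) are flagged as lumen
#' candidates. Everything above the surface (plus a small offset) is
#' excluded, and holes inside candidates are filled.
#'
#' @param slice numeric matrix, axial rows x lateral columns.
#' @param surface_rows optional 0-based surface row per column; detected
#'   with [detect_surface()] when `NULL`.
#' @param ratio intensity ratio to the per-depth median below which a
#'   pixel is a lumen candidate.
#' @param offset_rows rows below the surface excluded from segmentation
#'   (specular line and immediate sub-surface).
#' @param reference optional per-depth expected intensity profile (index 1
#'   = depth 0 below the surface), typically pooled over a whole volume by
#'   [segment_volume()]; when `NULL` the per-depth median of this slice is
#'   used. A pooled reference is robust to single structures that dominate
#'   one depth of one slice.
#' @param min_level reliability floor: depths whose expected intensity
#'   falls below this are too attenuated to segment and are excluded.
#'   Voxels with intensity exactly 0 (the fill of unobserved voxels) are
#'   also excluded.
#' @param lower,upper,m_persist surface-detection parameters.
#' @return Logical matrix of the slice shape (empty mask when nothing is
#'   segmentable).
#' @export
segment_lumens <- function(slice, surface_rows = NULL, ratio = 0.5,
                           offset_rows = 4L, reference = NULL,
                           min_level = 0.05, lower = 0.15, upper = 0.85,
                           m_persist = 3L) {
  nr <- nrow(slice); nc <- ncol(slice)
  if (is.null(surface_rows))
    surface_rows <- detect_surface(slice, lower, upper, m_persist)$surface_rows
  mask <- matrix(FALSE, nr, nc)
  ok <- which(!is.na(surface_rows))
  if (length(ok) < 3L) return(mask)
  # align columns by surface: depth index = row - surface_row
  depth <- matrix(0:(nr - 1), nr, nc) -
    matrix(surface_rows, nr, nc, byrow = TRUE)
  below <- depth > offset_rows
  below[, -ok] <- FALSE
  if (!any(below)) return(mask)
  dmax <- max(depth[below])
  dep_idx <- depth[below] + 1L
  if (is.null(reference)) {
    reference <- rep(NA_real_, dmax + 1L)
    sp <- split(slice[below], dep_idx)
    reference[as.integer(names(sp))] <- vapply(sp, median, numeric(1))
  } else if (length(reference) < dmax + 1L) {
    reference <- c(reference, rep(NA_real_, dmax + 1L - length(reference)))
  }
  expect <- matrix(NA_real_, nr, nc)
  expect[below] <- reference[dep_idx]
  cand <- below & is.finite(expect) & expect > min_level &
    slice < ratio * expect & slice > 0
  cand[is.na(cand)] <- FALSE
  if (any(cand)) {
    filled <- as.matrix(EBImage::fillHull(matrix(as.integer(cand), nr, nc)))
    mask <- filled > 0
  }
  mask
}

#' Segment tubule lumens in every slice of a tissue volume
#'
#' Applies a slice segmenter to each elevational (y-z) slice of the
#' reconstructed volume, producing the binary lumen mask volume. The
#' expected depth-decay profile handed to the default segmenter is pooled
#' over the whole volume (per-depth median across all slices), so a
#' single large structure cannot masquerade as the background decay of
#' its own slice. The segmenter is pluggable: any function with the
#' signature of [segment_lumens()] (a trained network wrapper, for
#' instance) can stand in for the classical default.
#'
#' @param volume A `tissue_volume`.
#' @param segmenter function `(slice, surface_rows, reference, ...)`
#'   returning a logical matrix.
#' @param offset_rows rows below the surface excluded from the profile
#'   and from segmentation.
#' @param lower,upper,m_persist surface-detection parameters.
#' @param ... passed to the segmenter.
#' @return Logical 3D array with the volume's dimensions (x, y, z).
#' @export
segment_volume <- function(volume, segmenter = segment_lumens,
                           offset_rows = 4L, lower = 0.15, upper = 0.85,
                           m_persist = 3L, ...) {
  V <- volume_values(volume)
  d <- dim(V)
  msk <- array(FALSE, d)
  nz <- d[3]
  slices <- vector("list", d[1])
  srows <- vector("list", d[1])
  # pass 1: surfaces, and a pooled per-depth intensity histogram
  nb <- 256L
  H <- matrix(0, nz, nb)
  for (i in seq_len(d[1])) {
    # slice to B-scan orientation: rows = depth (top of image = high z)
    sl <- t(V[i, , , drop = TRUE])[nz:1, , drop = FALSE]
    slices[[i]] <- sl
    sr <- detect_surface(sl, lower, upper, m_persist)$surface_rows
    srows[[i]] <- sr
    ok <- !is.na(sr)
    if (!any(ok)) next
    depth <- matrix(0:(nz - 1), nz, d[2]) - matrix(sr, nz, d[2], byrow = TRUE)
    use <- depth > offset_rows & sl > 0
    use[, !ok] <- FALSE
    if (!any(use)) next
    bin <- pmin(floor(sl[use] * nb), nb - 1L)
    # histogram row k holds samples at depth k-1 (reference[depth + 1])
    H <- H + matrix(tabulate(depth[use] * nb + bin + 1L,
                             nbins = nz * nb), nz, nb, byrow = TRUE)
  }
  # per-depth median from the cumulative histogram
  reference <- rep(NA_real_, nz)
  tot <- rowSums(H)
  for (dep in which(tot > 0)) {
    cs <- cumsum(H[dep, ])
    reference[dep] <- (which(cs >= tot[dep] / 2)[1] - 0.5) / nb
  }
  for (i in seq_len(d[1])) {
    m <- segmenter(slices[[i]], surface_rows = srows[[i]],
                   reference = reference, offset_rows = offset_rows, ...)
    msk[i, , ] <- t(m[nz:1, , drop = FALSE])
  }
  msk
}

# Fill background components (holes) smaller than a_min pixels that do not
# touch the image border.
area_closing_slice <- function(m, a_min) {
  if (!any(!m)) return(m)
  lab <- as.matrix(EBImage::bwlabel(matrix(as.integer(!m), nrow(m), ncol(m))))
  if (max(lab) == 0L) return(m)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  areas <- tabulate(lab, nbins = max(lab))
  fill <- setdiff(which(areas < a_min), border)
  if (length(fill)) m[lab %in% fill] <- TRUE
  m
}

# Remove foreground components smaller than a_min pixels.
area_opening_slice <- function(m, a_min) {
  if (!any(m)) return(m)
  lab <- as.matrix(EBImage::bwlabel(matrix(as.integer(m), nrow(m), ncol(m))))
  areas <- tabulate(lab, nbins = max(lab))
  drop <- which(areas < a_min)
  if (length(drop)) m[lab %in% drop] <- FALSE
  m
}

#' Morphologically clean a lumen mask volume
#'
#' Slice-by-slice area closing (fill enclosed holes smaller than `A_c`
#' pixels) followed by area opening (remove components smaller than `A_o`
#' pixels), enforcing shape consistency of the segmented lumens. The
#' output is always a subset of the closed input.
#'
#' @param mask logical 3D array (x, y, z) or a single logical matrix.
#' @param A_c,A_o area thresholds in pixels.
#' @return Cleaned mask of the input shape.
#' @export
clean_mask <- function(mask, A_c = 20L, A_o = 20L) {
  one <- function(m) area_opening_slice(area_closing_slice(m, A_c), A_o)
  if (is.matrix(mask)) return(one(mask))
  d <- dim(mask)
  out <- mask
  nz <- d[3]
  for (i in seq_len(d[1])) {
    sl <- t(mask[i, , , drop = TRUE])[nz:1, , drop = FALSE]
    out[i, , ] <- t(one(sl)[nz:1, , drop = FALSE])
  }
  out
}

# Zhang-Suen binary thinning to a 1-pixel skeleton.
skeletonize <- function(m) {
  m <- m * 1L
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3L || nc < 3L) return(m > 0L)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  sh <- function(p, dr, dc) p[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p <- pad
      P2 <- sh(p, -1, 0); P3 <- sh(p, -1, 1); P4 <- sh(p, 0, 1)
      P5 <- sh(p, 1, 1);  P6 <- sh(p, 1, 0);  P7 <- sh(p, 1, -1)
      P8 <- sh(p, 0, -1); P9 <- sh(p, -1, -1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      seqs <- list(P2, P3, P4, P5, P6, P7, P8, P9, P2)
      A <- 0L
      for (k in 1:8) A <- A + (seqs[[k]] == 0L & seqs[[k + 1L]] == 1L)
      core <- sh(p, 0, 0) == 1L & B >= 2L & B <= 6L & A == 1L
      del <- if (phase == 1L)
        core & (P2 * P4 * P6 == 0L) & (P4 * P6 * P8 == 0L)
      else
        core & (P2 * P4 * P8 == 0L) & (P2 * P6 * P8 == 0L)
      # a lone 2x2 block satisfies both subiteration tests at once; never
      # let a deletion wipe out the whole remaining structure
      if (any(del) && sum(del) < sum(pad)) {
        pad[2:(nr + 1L), 2:(nc + 1L)][del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  pad[2:(nr + 1L), 2:(nc + 1L)] > 0L
}

#' Measure lumen diameters in a cleaned mask volume
#'
#' Per slice and per connected component, the component is skeletonized
#' (centerline) and its diameter taken as the mean over skeleton pixels of
#' twice the Euclidean distance-transform value, converted to micrometres
#' with the lateral pixel pitch. A component whose skeleton is empty (a
#' single pixel) gets one pixel equivalent.
#'
#' @param mask logical 3D array (x, y, z) from [clean_mask()], or a single
#'   logical matrix (treated as one slice).
#' @param pitch_mm in-plane pixel pitch used for the um conversion
#'   (lateral voxel size).
#' @param origin,voxel_size optional volume placement used to report
#'   centroids in base-frame mm.
#' @param exclude_border drop components touching the lateral slice edges:
#'   lumens clipped by the B-scan field of view would otherwise bias the
#'   diameter statistics low.
#' @return Data frame of lumen records: `slice`, `component`, `cx, cy`
#'   (base mm when placement is given, else pixel units), `diameter_um`,
#'   `area_px`.
#' @export
measure_diameters <- function(mask, pitch_mm, origin = c(0, 0, 0),
                              voxel_size = c(1, 1, 1),
                              exclude_border = TRUE) {
  if (is.matrix(mask)) {
    d <- dim(mask)
    mask <- array(mask, c(1L, d[1], d[2]))
    voxel_size <- c(1, voxel_size[1], voxel_size[2])
  }
  d <- dim(mask)
  recs <- list()
  for (i in seq_len(d[1])) {
    sl <- mask[i, , , drop = TRUE] * 1L      # y rows, z cols; in-plane
    if (!any(sl > 0L)) next
    lab <- as.matrix(EBImage::bwlabel(sl))
    dmap <- as.matrix(EBImage::distmap(sl))
    clipped <- if (exclude_border) unique(c(lab[1, ], lab[d[2], ]))
               else integer(0)
    for (comp in seq_len(max(lab))) {
      if (comp %in% clipped) next
      px <- which(lab == comp, arr.ind = TRUE)
      if (!nrow(px)) next
      # skeletonize on the component's padded bounding box
      rr <- range(px[, 1]); cc <- range(px[, 2])
      sub <- lab[max(1, rr[1] - 1):min(d[2], rr[2] + 1),
                 max(1, cc[1] - 1):min(d[3], cc[2] + 1), drop = FALSE] == comp
      sk <- if (nrow(px) > 1L) skeletonize(sub) else matrix(FALSE, 1, 1)
      skidx <- which(sk, arr.ind = TRUE)
      if (nrow(skidx)) {
        skidx[, 1] <- skidx[, 1] + max(1, rr[1] - 1) - 1L
        skidx[, 2] <- skidx[, 2] + max(1, cc[1] - 1) - 1L
        diam_px <- mean(2 * dmap[skidx])
      } else diam_px <- 1
      recs[[length(recs) + 1L]] <- data.frame(
        slice = i, component = comp,
        cx = origin[1] + (i - 0.5) * voxel_size[1],
        cy = origin[2] + (mean(px[, 1]) - 0.5) * voxel_size[2],
        diameter_um = diam_px * pitch_mm * 1000,
        area_px = nrow(px))
    }
  }
  if (!length(recs))
    return(data.frame(slice = integer(0), component = integer(0),
                      cx = numeric(0), cy = numeric(0),
                      diameter_um = numeric(0), area_px = integer(0)))
  do.call(rbind, recs)
}

# Cubic-convolution (Catmull-Rom, a = -0.5) interpolation weights from k
# input cell centres to n output cell centres spanning the same interval.
cubic_weights <- function(k, n) {
  a <- -0.5
  kern <- function(t) {
    t <- abs(t)
    ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
           ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
  }
  pos <- ((seq_len(n) - 0.5) / n) * k + 0.5   # continuous input index
  W <- matrix(0, n, k)
  for (i in seq_len(n)) {
    base <- floor(pos[i])
    for (m in (base - 1L):(base + 2L)) {
      w <- kern(pos[i] - m)
      mc <- min(max(m, 1L), k)                # clamp = replicate border
      W[i, mc] <- W[i, mc] + w
    }
  }
  W
}

#' Lumen-diameter map (DIAM)
#'
#' Divides the top-view region of interest into a k x k grid, averages the
#' diameters of the lumens whose centroid falls in each cell, fills empty
#' cells from their nearest non-empty cell, and upsamples back to the full
#' grid size by bi-cubic interpolation.
#'
#' @param records lumen records from [measure_diameters()] (centroids in
#'   base-frame mm).
#' @param dims_xy integer length-2 output grid size (elevational, lateral).
#' @param origin_xy,pitch_xy placement of the output grid, mm.
#' @param k number of block cells per axis.
#' @return A `parameter_map` of kind `"DIAM"` (values in um); all-invalid
#'   when there are no lumen records.
#' @export
diam_map <- function(records, dims_xy, origin_xy, pitch_xy, k = 10L) {
  if (k < 1L) stop("k must be at least 1")
  dims_xy <- as.integer(dims_xy)
  if (!nrow(records)) {
    v <- matrix(NA_real_, dims_xy[1], dims_xy[2])
    return(parameter_map(v, matrix(FALSE, dims_xy[1], dims_xy[2]),
                         origin_xy, pitch_xy, kind = "DIAM"))
  }
  span <- dims_xy * pitch_xy
  ci <- pmin(pmax(ceiling((records$cx - origin_xy[1]) / span[1] * k), 1L), k)
  cj <- pmin(pmax(ceiling((records$cy - origin_xy[2]) / span[2] * k), 1L), k)
  cell <- matrix(NA_real_, k, k)
  agg <- rowsum(cbind(records$diameter_um, 1), ci + (cj - 1L) * k)
  at <- as.integer(rownames(agg))
  cell[at] <- agg[, 1] / agg[, 2]
  # nearest-non-empty fill before upsampling
  if (anyNA(cell)) {
    filledpos <- which(!is.na(cell), arr.ind = TRUE)
    emptypos <- which(is.na(cell), arr.ind = TRUE)
    for (e in seq_len(nrow(emptypos))) {
      d2 <- (filledpos[, 1] - emptypos[e, 1])^2 +
        (filledpos[, 2] - emptypos[e, 2])^2
      nearest <- filledpos[which.min(d2), , drop = FALSE]
      cell[emptypos[e, 1], emptypos[e, 2]] <- cell[nearest]
    }
  }
  Wx <- cubic_weights(k, dims_xy[1])
  Wy <- cubic_weights(k, dims_xy[2])
  up <- Wx %*% cell %*% t(Wy)
  parameter_map(up, matrix(TRUE, dims_xy[1], dims_xy[2]),
                origin_xy, pitch_xy, kind = "DIAM")
}

#' Top-view projection of a mask volume
#'
#' @param mask logical 3D array (x, y, z).
#' @return Numeric matrix (x, y): 1 where any voxel along z is set.
#' @export
mask_top_view <- function(mask) {
  apply(mask, c(1, 2), function(v) as.numeric(any(v)))
}
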