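#' @importFrom tiff readTIFF writeTIFF
#' @importFrom jsonlite read_json write_json
NULL

# Float rasters are stored range-normalized in [0,1] TIFFs with the true
# range recorded in the JSON sidecar, so arbitrary physical units survive
# the round trip exactly (up to float precision).
normalize_raster <- function(m) {
  rng <- range(m[is.finite(m)], 0, 1)
  list(data = pmin(pmax((m - rng[1]) / max(diff(rng), 1e-30), 0), 1),
       range = rng)
}

#' Write a tracked scan to disk
#'
#' Produces the on-disk dialect used throughout: a multi-page 32-bit float
#' TIFF of B-scans, a pose log CSV (`timestamp_s, r00..r22, tx_mm, ty_mm,
#' tz_mm`), a JSON sidecar with the pixel geometry, and the controller
#' telemetry CSV.
#'
#' @param scan A `tracked_scan`.
#' @param dir output directory (created if needed).
#' @param stem file stem.
#' @return Named character vector of the files written, invisibly.
#' @export
write_tracked_scan <- function(scan, dir, stem = sprintf("line%02d", scan$line)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stack <- file.path(dir, paste0(stem, ".tif"))
  posecsv <- file.path(dir, paste0(stem, "_poses.csv"))
  sidecar <- file.path(dir, paste0(stem, ".json"))
  telecsv <- file.path(dir, paste0(stem, "_telemetry.csv"))
  writeTIFF(scan$frames, stack, bits.per.sample = 32L)
  write_pose_log(scan$poses, posecsv)
  write_json(list(res_lateral = scan$geom$res_lateral,
                  res_axial = scan$geom$res_axial,
                  n_lateral = scan$geom$n_lateral,
                  n_axial = scan$geom$n_axial,
                  line = scan$line, speckle_sd = scan$speckle_sd,
                  seed = scan$seed),
             sidecar, auto_unbox = TRUE, digits = NA)
  write.csv(scan$telemetry, telecsv, row.names = FALSE)
  invisible(c(stack = stack, poses = posecsv, sidecar = sidecar,
              telemetry = telecsv))
}

#' Read a tracked scan from disk
#'
#' @param stack_path multi-page TIFF of B-scans.
#' @param pose_path pose log CSV.
#' @param sidecar_path JSON sidecar with the pixel geometry.
#' @return A `tracked_scan`.
#' @export
read_tracked_scan <- function(stack_path, pose_path, sidecar_path) {
  side <- read_json(sidecar_path, simplifyVector = TRUE)
  need <- c("res_lateral", "res_axial", "n_lateral", "n_axial")
  missing <- setdiff(need, names(side))
  if (length(missing))
    stop("sidecar is missing fields: ", paste(missing, collapse = ", "))
  geom <- pixel_geometry(side$res_lateral, side$res_axial,
                         side$n_lateral, side$n_axial)
  frames <- readTIFF(stack_path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  poses <- read_pose_log(pose_path)
  if (length(frames) != length(poses))
    stop("frame/pose count mismatch: ", length(frames), " frame(s) vs ",
         length(poses), " pose row(s)")
  structure(list(frames = frames, poses = poses, geom = geom,
                 telemetry = NULL, line = side$line %||% 1L,
                 plan = NULL, speckle_sd = side$speckle_sd %||% NA_real_,
                 seed = side$seed %||% NULL),
            class = "tracked_scan")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a parameter map
#'
#' Values go to `<prefix>.tif` (32-bit float, range-normalized with the
#' range in the sidecar), validity to `<prefix>_valid.tif` (8-bit), and
#' kind/origin/pitch/range to `<prefix>.json`.
#'
#' @param map A `parameter_map`.
#' @param prefix path prefix (no extension).
#' @return Named character vector of files written, invisibly.
#' @export
write_map <- function(map, prefix) {
  v <- map$values
  v[!map$valid] <- 0
  nrm <- normalize_raster(v)
  writeTIFF(nrm$data, paste0(prefix, ".tif"), bits.per.sample = 32L)
  writeTIFF(matrix(as.numeric(map$valid), nrow(v), ncol(v)),
            paste0(prefix, "_valid.tif"), bits.per.sample = 8L)
  write_json(list(kind = map$kind, origin_xy = map$origin_xy,
                  pitch_xy = map$pitch_xy, value_range = nrm$range),
             paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(c(values = paste0(prefix, ".tif"),
              valid = paste0(prefix, "_valid.tif"),
              sidecar = paste0(prefix, ".json")))
}

#' Read a parameter map written by [write_map()]
#'
#' @param prefix path prefix (no extension).
#' @return A `parameter_map`.
#' @export
read_map <- function(prefix) {
  side <- read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  nd <- readTIFF(paste0(prefix, ".tif"))
  valid <- readTIFF(paste0(prefix, "_valid.tif")) > 0.5
  vals <- side$value_range[1] + nd * diff(side$value_range)
  vals[!valid] <- NA_real_
  parameter_map(vals, valid, side$origin_xy, side$pitch_xy, side$kind)
}

#' Serialize a synthetic scene
#'
#' JSON metadata plus range-normalized float TIFF rasters of the height
#' field and the parenchyma extinction field sampled on a regular lattice.
#'
#' @param scene An `oct_scene`.
#' @param dir output directory.
#' @param pitch sampling lattice pitch, mm.
#' @return Named character vector of files written, invisibly.
#' @export
write_scene <- function(scene, dir, pitch = 0.05) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hg <- scene_height_grid(scene, pitch)
  mu <- t(vapply(hg$xs, function(x) scene$mu_fun(x, hg$ys),
                 numeric(length(hg$ys))))
  hn <- normalize_raster(hg$z); mn <- normalize_raster(mu)
  writeTIFF(hn$data, file.path(dir, "height.tif"), bits.per.sample = 32L)
  writeTIFF(mn$data, file.path(dir, "attenuation.tif"), bits.per.sample = 32L)
  meta <- list(kind = scene$kind, extent = scene$extent, pitch = pitch,
               height_range = hn$range, mu_range = mn$range,
               capsule_mu = scene$capsule_mu,
               capsule_thickness = scene$capsule_thickness,
               background_level = scene$background_level,
               surface_reflectivity = scene$surface_reflectivity,
               subsurface_peak = scene$subsurface_peak,
               rng_seed = scene$rng_seed,
               ellipsoids = scene$ellipsoids, metadata = scene$metadata)
  write_json(meta, file.path(dir, "scene.json"), auto_unbox = TRUE,
             digits = NA)
  invisible(c(meta = file.path(dir, "scene.json"),
              height = file.path(dir, "height.tif"),
              attenuation = file.path(dir, "attenuation.tif")))
}

#' Read a serialized scene
#'
#' Rebuilds the scene with bilinear height and attenuation fields sampled
#' from the stored rasters.
#'
#' @param dir directory written by [write_scene()].
#' @return An `oct_scene`.
#' @export
read_scene <- function(dir) {
  meta <- read_json(file.path(dir, "scene.json"), simplifyVector = TRUE)
  z <- readTIFF(file.path(dir, "height.tif"))
  mu <- readTIFF(file.path(dir, "attenuation.tif"))
  z <- meta$height_range[1] + z * diff(meta$height_range)
  mu <- meta$mu_range[1] + mu * diff(meta$mu_range)
  xs <- seq(meta$extent[1], meta$extent[2], by = meta$pitch)
  ys <- seq(meta$extent[3], meta$extent[4], by = meta$pitch)
  hf <- bilinear_grid(xs, ys, z)
  mf <- bilinear_grid(xs, ys, mu)
  ell <- if (is.null(meta$ellipsoids) || !length(meta$ellipsoids))
    empty_ellipsoids() else as.data.frame(meta$ellipsoids)
  synthetic_scene(extent = meta$extent, height_fun = hf, mu_fun = mf,
                  capsule_mu = meta$capsule_mu,
                  capsule_thickness = meta$capsule_thickness,
                  ellipsoids = ell,
                  background_level = meta$background_level,
                  surface_reflectivity = meta$surface_reflectivity,
                  subsurface_peak = meta$subsurface_peak,
                  rng_seed = meta$rng_seed,
                  metadata = as.list(meta$metadata), kind = meta$kind)
}
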