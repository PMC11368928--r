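#' Scan a whole sample: land and execute every scanline
#'
#' @param scene An `oct_scene`.
#' @param plan A `scan_plan`.
#' @param geom A `pixel_geometry`.
#' @param state A `controller_state`.
#' @param speckle_sd,seed renderer noise controls (the seed is offset per
#'   line so lines have independent but reproducible speckle).
#' @param ... surface-detection parameters passed through.
#' @return List of `tracked_scan`, one per scanline.
#' @export
scan_sample <- function(scene, plan, geom, state = controller_state(),
                        speckle_sd = 0, seed = NULL, ...) {
  lapply(seq_len(plan$n), function(i)
    execute_scanline(scene, plan, i, geom, state,
                     speckle_sd = speckle_sd, seed = seed, ...))
}

build_scene_from_config <- function(cfg, seed = NULL) {
  kind <- cfg$kind %||% "kidney"
  args <- cfg$args %||% list()
  switch(kind,
         letter_phantom = do.call(make_letter_phantom, args),
         kidney = {
           if (!is.null(seed) && is.null(args$seed)) args$seed <- seed
           do.call(make_kidney_scene, args)
         },
         stop("unknown scene kind: ", kind))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full scan-and-map pipeline
#'
#' Executes plan, landing, closed-loop scanning per line, reconstruction,
#' the requested parameter maps, stitching, optionally the speed sweep and
#' the phantom accuracy evaluation, writing every artifact plus a manifest
#' with checksums under `out_dir`. Reruns with the same config and seed
#' are byte-identical.
#'
#' @param config nested list: `scene` (`kind`, `args`), `geometry` (fields
#'   of [pixel_geometry()]), `plan` (fields of [plan_scanlines()] except
#'   geometry), `controller` (fields of [controller_state()]),
#'   `speckle_sd`, `maps` (subset of `"depm", "atcm", "diam"`),
#'   `voxel_size` (optional), `diam` (`A_c`, `A_o`, `k`, `ratio`),
#'   `sweep` (`v0`, `v1`, `step`) or `NULL`, `evaluate` (logical; phantom
#'   accuracy).
#' @param out_dir output directory.
#' @param seed integer master seed.
#' @return Invisibly, a list with the stitched maps, lumen records, sweep
#'   table, accuracy report and manifest path.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  geom <- stage("geometry", do.call(pixel_geometry, config$geometry %||% list()))
  scene <- stage("scene", build_scene_from_config(config$scene, seed))
  plan <- stage("planning", do.call(plan_scanlines,
                                    c(config$plan, list(geom = geom))))
  state <- stage("controller", do.call(controller_state,
                                       config$controller %||% list()))
  speckle_sd <- config$speckle_sd %||% 0

  files <- c(files, stage("scene-io", write_scene(scene, file.path(out_dir, "scene"))))
  write_plan(plan, file.path(out_dir, "plan.json"))
  files <- c(files, file.path(out_dir, "plan.json"))

  scans <- stage("scan", scan_sample(scene, plan, geom, state,
                                     speckle_sd = speckle_sd, seed = seed))
  for (s in scans)
    files <- c(files, write_tracked_scan(s, file.path(out_dir, "scans")))

  wanted <- config$maps %||% c("depm")
  voxel_size <- config$voxel_size
  dcfg <- config$diam %||% list()
  per_line <- stage("reconstruct", lapply(scans, function(s)
    voxelize_scan(s, voxel_size = voxel_size)))

  out <- list()
  if ("depm" %in% wanted) {
    maps <- stage("depm", lapply(per_line, depm))
    out$depm <- stage("stitch", stitch_maps(maps))
    files <- c(files, write_map(out$depm, file.path(out_dir, "depm")))
  }
  if ("atcm" %in% wanted) {
    maps <- stage("atcm", lapply(scans, atcm))
    out$atcm <- stage("stitch", stitch_maps(maps))
    files <- c(files, write_map(out$atcm, file.path(out_dir, "atcm")))
  }
  if ("diam" %in% wanted) {
    out$diam_records <- stage("diam", {
      recs <- lapply(per_line, function(vol) {
        msk <- segment_volume(vol, ratio = dcfg$ratio %||% 0.5)
        msk <- clean_mask(msk, dcfg$A_c %||% 20L, dcfg$A_o %||% 20L)
        measure_diameters(msk, pitch_mm = vol$voxel_size[2],
                          origin = vol$origin, voxel_size = vol$voxel_size)
      })
      do.call(rbind, recs)
    })
    ref <- if (!is.null(out$depm)) out$depm else {
      v <- per_line[[1]]
      parameter_map(matrix(0, dim(v$sums)[1], dim(v$sums)[2]),
                    matrix(TRUE, dim(v$sums)[1], dim(v$sums)[2]),
                    v$origin[1:2], v$voxel_size[1:2], "DIAM")
    }
    out$diam <- stage("diam-map", diam_map(out$diam_records,
                                           dims_xy = dim(ref$values),
                                           origin_xy = ref$origin_xy,
                                           pitch_xy = ref$pitch_xy,
                                           k = dcfg$k %||% 10L))
    files <- c(files, write_map(out$diam, file.path(out_dir, "diam")))
    rpath <- file.path(out_dir, "diam_records.csv")
    write.csv(out$diam_records, rpath, row.names = FALSE)
    files <- c(files, rpath)
  }

  if (!is.null(config$sweep)) {
    sw <- config$sweep
    target <- out$atcm %||% out$depm
    if (!is.null(target)) {
      out$sweep <- stage("sweep", speed_sweep(
        target, v_ref = plan$v_x,
        speeds = speed_grid(sw$v0 %||% plan$v_x,
                            sw$v1 %||% (8.5 * plan$v_x),
                            sw$step %||% 0.5)))
      spath <- file.path(out_dir, "sweep.csv")
      write.csv(out$sweep, spath, row.names = FALSE)
      files <- c(files, spath)
    }
  }

  if (isTRUE(config$evaluate) && !is.null(out$depm) &&
      scene$kind == "letter_phantom") {
    out$accuracy <- stage("evaluate", evaluate_depm_accuracy(out$depm, scene))
    apath <- file.path(out_dir, "accuracy.json")
    write_json(list(summary = as.list(out$accuracy$summary),
                    per_glyph = out$accuracy$per_glyph),
               apath, auto_unbox = TRUE, digits = NA)
    files <- c(files, apath)
  }

  manifest <- list(
    version = as.character(utils::packageVersion("roctscan")),
    seed = seed, config = config,
    files = lapply(unname(files), function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  mpath <- file.path(out_dir, "manifest.json")
  write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  out$manifest <- mpath
  invisible(out)
}
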