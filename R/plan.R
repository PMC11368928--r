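#' Plan parallel scanlines over a sample footprint
#'
#' Scanlines run along the base-frame x axis and are spaced along y so that
#' the lateral B-scan fields of view of adjacent lines overlap by `W_ol`.
#' The number of lines is `n = ceiling(W / (W_OCT - W_ol))`, valid under the
#' constraint `W_OCT > 2 * W_ol > 0`.
#'
#' @param x_st,y_st,z_st start of the first scanline in base-frame mm;
#'   `z_st` is the entry altitude, high enough that the sample is initially
#'   out of the axial field of view.
#' @param L scanline length along x, mm.
#' @param W lateral extent to cover along y, mm.
#' @param W_ol lateral overlap between adjacent lines, mm.
#' @param geom `pixel_geometry` from which the lateral FOV `W_OCT` is
#'   derived unless overridden.
#' @param W_OCT optional explicit lateral FOV, mm.
#' @param v_x scan speed along the line, mm/s.
#' @param frame_rate B-scan acquisition rate, Hz.
#' @return An object of class `scan_plan` with the line count `n`, the per
#'   line starting y coordinates `line_y`, and the elevational pitch
#'   `v_x / frame_rate` as `pitch_elev`.
#' @export
plan_scanlines <- function(x_st, y_st, z_st, L, W, W_ol,
                           geom = pixel_geometry(), W_OCT = NULL,
                           v_x = 0.6, frame_rate = 20) {
  if (L <= 0 || W <= 0) stop("L and W must be positive")
  if (v_x <= 0 || frame_rate <= 0) stop("v_x and frame_rate must be positive")
  if (is.null(W_OCT)) W_OCT <- geom$fov_lateral
  if (!(W_OCT > 2 * W_ol && W_ol > 0))
    stop("scanline constraint violated: need W_OCT > 2*W_ol > 0 (W_OCT = ",
         signif(W_OCT, 4), ", W_ol = ", signif(W_ol, 4), ")")
  n <- ceiling(W / (W_OCT - W_ol))
  structure(list(x_st = x_st, y_st = y_st, z_st = z_st, L = L, W = W,
                 W_ol = W_ol, W_OCT = W_OCT, n = as.integer(n),
                 v_x = v_x, frame_rate = frame_rate,
                 pitch_elev = v_x / frame_rate,
                 line_y = y_st + (seq_len(n) - 1) * (W_OCT - W_ol)),
            class = "scan_plan")
}

#' @export
print.scan_plan <- function(x, ...) {
  cat(sprintf("<scan_plan> %d line(s) of %.3g mm at %.3g mm/s, lateral step %.3g mm (overlap %.3g mm)\n",
              x$n, x$L, x$v_x, x$W_OCT - x$W_ol, x$W_ol))
  invisible(x)
}

#' Entry pose of a scanline
#'
#' The probe is positioned above the start of line `i` with the scanning
#' orientation `diag(1, -1, -1)`: probe z pointing down into the sample and
#' probe y anti-parallel to base y.
#'
#' @param plan A `scan_plan`.
#' @param i scanline index in `1..n`.
#' @param timestamp seconds attached to the pose.
#' @return An `oct_pose`.
#' @export
entry_pose <- function(plan, i, timestamp = 0) {
  if (i < 1 || i > plan$n) stop("scanline index out of range 1..", plan$n)
  pose(diag(c(1, -1, -1)),
       c(plan$x_st, plan$line_y[i], plan$z_st), timestamp)
}

#' Serialize a scan plan to JSON
#' @param plan A `scan_plan`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scan plan from JSON
#' @param path JSON file written by [write_plan()].
#' @return A `scan_plan`.
#' @export
read_plan <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  plan_scanlines(p$x_st, p$y_st, p$z_st, p$L, p$W, p$W_ol,
                 W_OCT = p$W_OCT, v_x = p$v_x, frame_rate = p$frame_rate)
}
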