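#' Pixel/voxel calibration
#'
#' Records the physical size of a pixel in the imaging plane and the axial
#' step between optical sections, and converts pixel or voxel measurements to
#' micrometres. Confocal spine stacks in this workflow use a voxel of
#' 0.066 x 0.066 x 0.2 um; cluster-analysis projections use 5/95 um/px
#' (a 95-px grow radius corresponds to 5 um).
#'
#' @param pixel_size_um Physical size of one pixel in x/y, in micrometres.
#' @param z_step_um Distance between optical sections, in micrometres.
#'   Defaults to `NA` for purely 2D analyses.
#' @return An object of class `calibration` with fields `pixel_size_um` and
#'   `z_step_um`.
#' @examples
#' cal <- calibration(pixel_size_um = 5 / 95)
#' cal$pixel_size_um * 95  # 5 um
#' @export
calibration <- function(pixel_size_um, z_step_um = NA_real_) {
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  }
  if (!is.na(z_step_um) && (!is.numeric(z_step_um) || z_step_um <= 0)) {
    stop("`z_step_um` must be positive when given", call. = FALSE)
  }
  structure(
    list(pixel_size_um = as.numeric(pixel_size_um),
         z_step_um = as.numeric(z_step_um)),
    class = "calibration"
  )
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> %.5f um/px (xy)", x$pixel_size_um))
  if (!is.na(x$z_step_um)) cat(sprintf(", z step %.3f um", x$z_step_um))
  cat("\n")
  invisible(x)
}

#' @rdname calibration
#' @param x Object to test or print.
#' @export
is_calibration <- function(x) inherits(x, "calibration")

#' Default calibration of cluster-analysis projections: a 95-px grow radius
#' spans 5 um, i.e. 5/95 um per pixel.
#' @rdname calibration
#' @export
cluster_calibration <- function() calibration(pixel_size_um = 5 / 95)

#' Voxel volume in cubic micrometres
#'
#' @param cal A [calibration()] with a z step.
#' @return Voxel volume in um^3.
#' @export
voxel_volume_um3 <- function(cal) {
  stopifnot(is_calibration(cal))
  if (is.na(cal$z_step_um)) stop("calibration has no z step", call. = FALSE)
  cal$pixel_size_um^2 * cal$z_step_um
}
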