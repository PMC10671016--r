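#' Sensor geometry
#'
#' Describes the pixel array of the implantable needle-type CMOS image sensor.
#' The default is the 40 x 90 pixel array with a 7.5 um pixel pitch read out at
#' 10 frames per second, giving a 300 um x 675 um imaging field that covers
#' most of the nucleus accumbens along the implantation axis.
#'
#' @param n_rows Number of pixel rows (short axis).
#' @param n_cols Number of pixel columns (long axis).
#' @param pixel_pitch Pixel pitch in micrometres.
#' @param fps Native acquisition rate of the sensor, frames per second.
#'
#' @return An object of class `sensor_geometry`.
#' @seealso [field_dimensions()]
#' @export
#' @examples
#' geom <- sensor_geometry()
#' field_dimensions(geom)
sensor_geometry <- function(n_rows = 40, n_cols = 90, pixel_pitch = 7.5,
                            fps = 10) {
  if (!is.numeric(n_rows) || length(n_rows) != 1L || n_rows < 1 ||
      n_rows != round(n_rows)) {
    stop("`n_rows` must be a single integer >= 1", call. = FALSE)
  }
  if (!is.numeric(n_cols) || length(n_cols) != 1L || n_cols < 1 ||
      n_cols != round(n_cols)) {
    stop("`n_cols` must be a single integer >= 1", call. = FALSE)
  }
  if (!is.numeric(pixel_pitch) || length(pixel_pitch) != 1L || pixel_pitch <= 0) {
    stop("`pixel_pitch` must be a single positive number (um)", call. = FALSE)
  }
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop("`fps` must be a single positive number (frames/s)", call. = FALSE)
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         pixel_pitch = pixel_pitch, fps = fps),
    class = "sensor_geometry"
  )
}

#' Physical size of the imaging field
#'
#' @param geometry A [sensor_geometry()] object.
#' @return Named numeric vector `c(height_um, width_um)`, i.e.
#'   `n_rows * pixel_pitch` by `n_cols * pixel_pitch`.
#' @export
#' @examples
#' field_dimensions(sensor_geometry(40, 90, 7.5))  # 300 x 675 um
field_dimensions <- function(geometry) {
  stopifnot(inherits(geometry, "sensor_geometry"))
  c(height_um = geometry$n_rows * geometry$pixel_pitch,
    width_um = geometry$n_cols * geometry$pixel_pitch)
}

#' @export
print.sensor_geometry <- function(x, ...) {
  fd <- field_dimensions(x)
  cat(sprintf("<sensor_geometry> %d x %d px, %.2f um pitch (%g x %g um), %g fps\n",
              x$n_rows, x$n_cols, x$pixel_pitch, fd[1], fd[2], x$fps))
  invisible(x)
}
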