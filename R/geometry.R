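#' Screen and viewing geometry
#'
#' Bundles the physical description of the recording setup: screen size in
#' centimetres, screen resolution in pixels and the (fixed) viewing distance.
#' All conversions between pixels and degrees of visual angle go through this
#' object. The defaults describe a 30.6 x 23.0 cm stimulus area viewed from
#' 52.5 cm, which subtends 32.5 x 24.7 degrees.
#'
#' @param screen_width_cm,screen_height_cm Physical extent of the stimulus
#'   area in centimetres.
#' @param screen_width_px,screen_height_px Resolution of the same area in
#'   pixels.
#' @param viewing_distance_cm Eye-to-screen distance in centimetres.
#'
#' @return An object of class `gaze_geometry`.
#' @examples
#' geom <- geometry()
#' pixels_to_degrees(30.6, geom, units = "cm")
#' @export
geometry <- function(screen_width_cm = 30.6,
                     screen_height_cm = 23.0,
                     screen_width_px = 640L,
                     screen_height_px = 480L,
                     viewing_distance_cm = 52.5) {
  vals <- c(screen_width_cm, screen_height_cm, screen_width_px,
            screen_height_px, viewing_distance_cm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all geometry fields must be positive and finite")
  }
  structure(
    list(
      screen_width_cm = screen_width_cm,
      screen_height_cm = screen_height_cm,
      screen_width_px = as.integer(screen_width_px),
      screen_height_px = as.integer(screen_height_px),
      viewing_distance_cm = viewing_distance_cm
    ),
    class = "gaze_geometry"
  )
}

#' @export
print.gaze_geometry <- function(x, ...) {
  cat(sprintf(
    "<gaze_geometry> %.1f x %.1f cm, %d x %d px, distance %.1f cm (%.1f x %.1f deg)\n",
    x$screen_width_cm, x$screen_height_cm,
    x$screen_width_px, x$screen_height_px, x$viewing_distance_cm,
    pixels_to_degrees(x$screen_width_cm, x, units = "cm"),
    pixels_to_degrees(x$screen_height_cm, x, units = "cm")
  ))
  invisible(x)
}

#' Convert screen extents to degrees of visual angle
#'
#' For a full extent centred on the line of sight the subtended angle is
#' `2 * atan(extent / (2 * distance))`. For per-sample velocity work the
#' small-angle linear factor at screen centre (`extent / distance` radians)
#' is the conventional approximation; select it with `method = "linear"`.
#'
#' @param extent Extent(s) to convert, in pixels (default) or centimetres.
#' @param geometry A [geometry()] object.
#' @param units `"px"` or `"cm"`.
#' @param axis `"x"` or `"y"`; selects the pixel pitch used when
#'   `units = "px"`.
#' @param method `"subtended"` (exact, full extent centred on screen) or
#'   `"linear"` (small-angle factor at screen centre).
#'
#' @return Angle(s) in degrees.
#' @examples
#' geom <- geometry()
#' pixels_to_degrees(23.0, geom, units = "cm", axis = "y")
#' @export
pixels_to_degrees <- function(extent, geometry, units = c("px", "cm"),
                              axis = c("x", "y"),
                              method = c("subtended", "linear")) {
  stopifnot(inherits(geometry, "gaze_geometry"))
  units <- match.arg(units)
  axis <- match.arg(axis)
  method <- match.arg(method)
  cm <- if (units == "cm") extent else extent * cm_per_px(geometry, axis)
  d <- geometry$viewing_distance_cm
  if (method == "subtended") {
    2 * atan(cm / (2 * d)) * 180 / pi
  } else {
    cm / d * 180 / pi
  }
}

cm_per_px <- function(geometry, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (axis == "x") {
    geometry$screen_width_cm / geometry$screen_width_px
  } else {
    geometry$screen_height_cm / geometry$screen_height_px
  }
}

# small-angle degrees-per-pixel factor at screen centre, per axis
deg_per_px <- function(geometry, axis = c("x", "y")) {
  axis <- match.arg(axis)
  cm_per_px(geometry, axis) / geometry$viewing_distance_cm * 180 / pi
}

screen_centre <- function(geometry) {
  c(x = geometry$screen_width_px / 2, y = geometry$screen_height_px / 2)
}
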