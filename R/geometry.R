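#' Describe the viewing geometry
#'
#' The HVS spatial filters are parameterized in degrees of visual angle; a
#' viewing geometry converts them to pixels via the number of display pixels
#' subtending one degree (samples per degree, spd). Provide either the
#' physical geometry (`distance_mm` and `pixel_pitch_mm`) or `spd` directly.
#'
#' Under the small-angle approximation,
#' `spd = (pi / 180) * distance_mm / pixel_pitch_mm`.
#'
#' @param distance_mm Observer-to-display distance in millimetres.
#' @param pixel_pitch_mm Physical pixel pitch of the display in millimetres.
#' @param spd Samples per degree given directly, bypassing the physical
#'   description. The package default of 35 spd corresponds to a 55 cm
#'   viewing distance on a typical 24-inch full-HD panel.
#' @return An object of class `viewing_geometry`.
#' @examples
#' g <- viewing_geometry(distance_mm = 550, pixel_pitch_mm = 0.2747)
#' samples_per_degree(g)
#' @export
viewing_geometry <- function(distance_mm = NULL, pixel_pitch_mm = NULL,
                             spd = NULL) {
  if (is.null(spd)) {
    if (is.null(distance_mm) || is.null(pixel_pitch_mm)) {
      stop("provide either spd or both distance_mm and pixel_pitch_mm")
    }
    if (distance_mm <= 0 || pixel_pitch_mm <= 0) {
      stop("distance_mm and pixel_pitch_mm must be positive")
    }
    spd <- (pi / 180) * distance_mm / pixel_pitch_mm
  } else {
    if (spd <= 0) stop("spd must be positive")
    distance_mm <- if (is.null(distance_mm)) NA_real_ else distance_mm
    pixel_pitch_mm <- if (is.null(pixel_pitch_mm)) NA_real_ else pixel_pitch_mm
  }
  structure(list(distance_mm = distance_mm, pixel_pitch_mm = pixel_pitch_mm,
                 samples_per_degree = spd),
            class = "viewing_geometry")
}

#' Samples of the display per degree of visual angle
#'
#' @param g A [viewing_geometry()].
#' @return Number of pixels subtending one degree of visual angle.
#' @export
samples_per_degree <- function(g) {
  if (!inherits(g, "viewing_geometry")) stop("expected a viewing_geometry")
  g$samples_per_degree
}

#' @export
print.viewing_geometry <- function(x, ...) {
  cat(sprintf("<viewing_geometry> distance=%s mm, pitch=%s mm, %.3f samples/degree\n",
              format(x$distance_mm), format(x$pixel_pitch_mm),
              x$samples_per_degree))
  invisible(x)
}
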