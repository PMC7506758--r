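#' Construct a raster image
#'
#' The package's in-memory image container: an `H x W x 3` numeric array in a
#' declared color space. Device RGB images carry values in `[0, 1]` regardless
#' of the bit depth they were decoded from, so downstream metric constants are
#' independent of source bit depth.
#'
#' @param pixels Numeric `H x W x 3` array (an `H x W` matrix is replicated
#'   across the three channels). Height and width must both be at least 3 so
#'   that 3x3 gradient operators are defined.
#' @param space Color space label, one of `"deviceRGB"`, `"XYZ"`, `"OPP"`
#'   (opponent), `"LAB"`.
#' @param range Nominal value range, a length-2 numeric; informational for
#'   spaces other than deviceRGB.
#' @return An object of class `raster_image` with fields `pixels`, `space`,
#'   `range`.
#' @examples
#' img <- raster_image(array(0.5, c(4, 6, 3)))
#' dim(img)
#' @export
raster_image <- function(pixels, space = c("deviceRGB", "XYZ", "OPP", "LAB"),
                         range = c(0, 1)) {
  space <- match.arg(space)
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3L) {
    stop("pixels must be an H x W x 3 array or an H x W matrix")
  }
  d <- dim(pixels)
  if (d[3L] != 3L) stop("image must have exactly 3 channels, got ", d[3L])
  if (d[1L] < 3L || d[2L] < 3L) {
    stop("image must be at least 3x3 pixels, got ", d[1L], "x", d[2L])
  }
  if (!all(is.finite(pixels))) stop("image contains non-finite values")
  structure(list(pixels = pixels, space = space, range = as.numeric(range)),
            class = "raster_image")
}

#' @export
dim.raster_image <- function(x) dim(x$pixels)

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raster_image> %dx%d, space=%s, range=[%g, %g]\n",
              d[1L], d[2L], x$space, x$range[1L], x$range[2L]))
  invisible(x)
}

is_raster_image <- function(x) inherits(x, "raster_image")

assert_space <- function(img, space) {
  if (!is_raster_image(img)) stop("expected a raster_image")
  if (img$space != space) {
    stop("expected image in ", space, " space, got ", img$space)
  }
  invisible(img)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
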