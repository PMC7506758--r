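#' Load a raster image from disk
#'
#' Reads PNG, TIFF or JPEG files into a device-RGB [raster_image] with values
#' scaled to `[0, 1]`. Grayscale inputs are replicated onto three channels;
#' an alpha channel, if present, is dropped.
#'
#' @param path Path to a PNG, TIFF or JPEG file.
#' @param assumed_range Optional maximum code value when the decoder returns
#'   values outside `[0, 1]` (e.g. raw-count TIFF planes). The default `NULL`
#'   trusts the decoder's normalization (8- and 16-bit files are divided by
#'   their maximum code value by the decoders themselves).
#' @return A [raster_image] in deviceRGB space.
#' @seealso [save_image()], [equalize_resolution()]
#' @export
load_image <- function(path, assumed_range = NULL) {
  if (!file.exists(path)) stop("image file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  reader <- switch(ext,
    png = png::readPNG,
    tif = ,
    tiff = function(p) tiff::readTIFF(p, convert = FALSE),
    jpg = ,
    jpeg = jpeg::readJPEG,
    stop("unsupported image format '", ext, "' for: ", path)
  )
  px <- tryCatch(reader(path), error = function(e) {
    stop("failed to decode image ", path, ": ", conditionMessage(e))
  })
  if (length(px) == 0L) stop("zero-sized image: ", path)
  if (is.matrix(px)) {
    px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  } else if (length(dim(px)) == 3L) {
    nc <- dim(px)[3L]
    if (nc == 2L) {
      px <- array(rep(px[, , 1L], 3L), dim = c(dim(px)[1:2], 3L))
    } else if (nc >= 4L) {
      px <- px[, , 1:3, drop = FALSE]
    }
  }
  if (!is.null(assumed_range)) px <- px / max(assumed_range)
  raster_image(px, space = "deviceRGB", range = c(0, 1))
}

#' Save a device-RGB image as PNG
#'
#' Values are clipped to `[0, 1]` and written as 8-bit PNG; an 8-bit image
#' loaded with [load_image()] round-trips bit-exactly.
#'
#' @param img A [raster_image] in deviceRGB space.
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  assert_space(img, "deviceRGB")
  png::writePNG(clip01(img$pixels), target = path)
  invisible(path)
}

#' Equalize the resolutions of an image pair
#'
#' Camouflage and background images must share dimensions before per-pixel
#' comparison. `resize` (default) resamples the second image to the first
#' image's dimensions with bicubic interpolation; `crop` takes the centered
#' common region of both. Pairs that already share dimensions pass through
#' untouched under either policy, so the operation is idempotent.
#'
#' @param a,b [raster_image] objects in the same color space.
#' @param policy `"resize"` or `"crop"`.
#' @return A list with elements `a` and `b` sharing identical `H x W`.
#' @examples
#' p <- generate_fixture(fixture_spec(seed = 1, patch_size = c(8, 8),
#'                                    background_size = c(16, 12)))
#' eq <- equalize_resolution(p$patch, p$background)
#' dim(eq$b)
#' @export
equalize_resolution <- function(a, b, policy = c("resize", "crop")) {
  policy <- match.arg(policy)
  if (!is_raster_image(a) || !is_raster_image(b)) stop("expected raster_image inputs")
  if (a$space != b$space) stop("images must be in the same color space")
  da <- dim(a$pixels); db <- dim(b$pixels)
  if (all(da[1:2] == db[1:2])) return(list(a = a, b = b))
  if (policy == "crop") {
    th <- min(da[1L], db[1L]); tw <- min(da[2L], db[2L])
    if (th < 3L || tw < 3L) {
      stop("crop overlap smaller than 3 pixels in one dimension (",
           th, "x", tw, ")")
    }
    list(a = raster_image(center_crop(a$pixels, th, tw), a$space, a$range),
         b = raster_image(center_crop(b$pixels, th, tw), b$space, a$range))
  } else {
    out <- array(0, c(da[1L], da[2L], 3L))
    for (c in 1:3) {
      out[, , c] <- resize_bicubic_plane(b$pixels[, , c], da[1L], da[2L])
    }
    if (a$space == "deviceRGB") out <- clip01(out)
    list(a = a, b = raster_image(out, b$space, b$range))
  }
}

center_crop <- function(px, th, tw) {
  d <- dim(px)
  r0 <- (d[1L] - th) %/% 2L
  c0 <- (d[2L] - tw) %/% 2L
  px[r0 + seq_len(th), c0 + seq_len(tw), , drop = FALSE]
}
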