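# Per-pair metrics: the color difference map/index (ICS, ICSI) in spatial
# CIELAB, and the texture similarity map/index (GMS, GMSD) from Sobel
# gradient magnitudes. Both indices pool their map with the population
# standard deviation (1/n), so a spatially uniform difference -- however
# large -- contributes nothing; see the package vignette for why that makes
# ICSI a structure metric rather than a mean-color metric.

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Sobel convolution kernels
#'
#' Horizontal (`sh`) and vertical (`sv`) 3x3 derivative kernels;
#' `sv` is the transpose of `sh`.
#' @return List with matrices `sh` and `sv`.
#' @export
sobel_kernels <- function() {
  sh <- matrix(c(-1, 0, 1,
                 -2, 0, 2,
                 -1, 0, 1), nrow = 3, byrow = TRUE)
  list(sh = sh, sv = t(sh))
}

difference_map <- function(values, kind = c("ICS", "GMS")) {
  kind <- match.arg(kind)
  if (!all(is.finite(values))) stop("difference map contains non-finite values")
  structure(list(values = values, kind = kind), class = "difference_map")
}

#' @export
print.difference_map <- function(x, ...) {
  cat(sprintf("<difference_map> kind=%s, %dx%d, mean=%.4g, sd=%.4g\n",
              x$kind, nrow(x$values), ncol(x$values), mean(x$values),
              pop_sd(x$values)))
  invisible(x)
}

#' Per-pixel color difference map in (S-)CIELAB
#'
#' Euclidean distance `sqrt(dL*^2 + da*^2 + db*^2)` between two Lab images
#' of identical dimensions; symmetric in its arguments.
#'
#' @param a,b `lab_image` objects of equal dimensions (use
#'   [equalize_resolution()] on the RGB inputs first if they differ).
#' @return A `difference_map` of kind `"ICS"`.
#' @export
ics_map <- function(a, b) {
  if (!inherits(a, "lab_image") || !inherits(b, "lab_image")) {
    stop("ics_map expects lab_image inputs")
  }
  if (!all(dim(a$pixels) == dim(b$pixels))) {
    stop("dimension mismatch; run equalize_resolution on the image pair first")
  }
  d <- a$pixels - b$pixels
  difference_map(sqrt(d[, , 1L]^2 + d[, , 2L]^2 + d[, , 3L]^2), "ICS")
}

#' Image color similarity index
#'
#' Population standard deviation (divide by the pixel count, no n-1
#' correction) of the ICS color-difference map. Zero for identical images
#' and, notably, for any spatially constant color offset.
#'
#' @param m A `difference_map` of kind `"ICS"`.
#' @return Non-negative scalar.
#' @export
icsi <- function(m) {
  if (!inherits(m, "difference_map") || m$kind != "ICS") {
    stop("icsi expects an ICS difference_map")
  }
  pop_sd(m$values)
}

#' Sobel gradient magnitude of an image
#'
#' Reduces the RGB image to a single plane (`"luminance"`: CIE Y from the
#' display characterization, consistent with the perceptual pipeline;
#' `"gray"`: Rec.601 luma `0.299 R + 0.587 G + 0.114 B` on the encoded
#' values), convolves it with the Sobel kernels under symmetric padding and
#' returns the per-pixel magnitude `sqrt(gh^2 + gv^2)`.
#'
#' @param img A deviceRGB [raster_image] (or a single-plane matrix, used
#'   as-is).
#' @param channel_policy `"luminance"` or `"gray"`.
#' @return `H x W` matrix of gradient magnitudes.
#' @export
gradient_magnitude <- function(img, channel_policy = c("luminance", "gray")) {
  channel_policy <- match.arg(channel_policy)
  plane <- if (is.matrix(img)) {
    img
  } else {
    assert_space(img, "deviceRGB")
    if (channel_policy == "luminance") {
      rgb_to_xyz(img)$pixels[, , 2L]
    } else {
      0.299 * img$pixels[, , 1L] + 0.587 * img$pixels[, , 2L] +
        0.114 * img$pixels[, , 3L]
    }
  }
  k <- sobel_kernels()
  gh <- conv2d_3x3(plane, k$sh)
  gv <- conv2d_3x3(plane, k$sv)
  sqrt(gh^2 + gv^2)
}

#' Gradient magnitude similarity map
#'
#' Per-pixel similarity `(2 Si Sj + c) / (Si^2 + Sj^2 + c)` of two gradient
#' magnitude fields, with stability constant `c > 0` keeping flat-vs-flat
#' regions at a perfect score of 1. Values lie in `(0, 1]`.
#'
#' @param si,sj Gradient magnitude matrices of equal dimensions.
#' @param c Stability constant; default 0.0026 for `[0, 1]`-ranged
#'   luminance.
#' @return A `difference_map` of kind `"GMS"`.
#' @export
gms_map <- function(si, sj, c = 0.0026) {
  if (c <= 0) stop("stability constant c must be positive")
  if (!all(dim(si) == dim(sj))) {
    stop("dimension mismatch; run equalize_resolution on the image pair first")
  }
  difference_map((2 * si * sj + c) / (si^2 + sj^2 + c), "GMS")
}

#' Gradient magnitude similarity deviation
#'
#' Population standard deviation of the GMS map; 0 for a structurally
#' identical pair, bounded above by 0.5.
#'
#' @param m A `difference_map` of kind `"GMS"`.
#' @return Scalar in `[0, 0.5]`.
#' @export
gmsd <- function(m) {
  if (!inherits(m, "difference_map") || m$kind != "GMS") {
    stop("gmsd expects a GMS difference_map")
  }
  pop_sd(m$values)
}

#' Metric computation settings for an image pair
#'
#' @param equalize_policy Resolution equalization policy, `"resize"` or
#'   `"crop"`; see [equalize_resolution()].
#' @param gms_c Stability constant of the GMS map.
#' @param channel_policy Plane used for gradients; see
#'   [gradient_magnitude()].
#' @param include_mean Also report the mean of the ICS map (`ics_mean`),
#'   useful because the standard-deviation pooling of ICSI assigns 0 to a
#'   uniformly wrong color.
#' @param keep_maps Attach the ICS and GMS maps to the result for
#'   diagnostics.
#' @param white Reference white for the Lab conversion.
#' @param params Spatial-filter parameters ([scielab_params()]).
#' @return A `pair_config` list.
#' @export
pair_config <- function(equalize_policy = c("resize", "crop"),
                        gms_c = 0.0026,
                        channel_policy = c("luminance", "gray"),
                        include_mean = FALSE, keep_maps = FALSE,
                        white = white_d65(), params = scielab_params()) {
  structure(list(equalize_policy = match.arg(equalize_policy),
                 gms_c = gms_c,
                 channel_policy = match.arg(channel_policy),
                 include_mean = include_mean, keep_maps = keep_maps,
                 white = white, params = params),
            class = "pair_config")
}

#' Color and texture metrics for one camouflage/background pair
#'
#' Equalizes the pair's resolution, transforms both images through the
#' spatial CIELAB pipeline to obtain ICSI, and compares Sobel gradient
#' magnitudes to obtain GMSD. Both metrics are exactly 0 when the two
#' images are identical.
#'
#' @param camo,bg deviceRGB [raster_image] objects.
#' @param geom A [viewing_geometry()].
#' @param config A [pair_config()].
#' @return A `metric_result` list with `icsi`, `gmsd` (and `ics_mean`,
#'   `maps` when requested).
#' @examples
#' fx <- generate_fixture(fixture_spec(seed = 3, patch_size = c(16, 16),
#'                                     background_size = c(16, 16)))
#' compute_pair(fx$patch, fx$patch)$icsi
#' @export
compute_pair <- function(camo, bg, geom = viewing_geometry(spd = 35),
                         config = pair_config()) {
  eq <- equalize_resolution(camo, bg, policy = config$equalize_policy)
  lab_a <- scielab_lab(eq$a, geom, white = config$white, params = config$params)
  lab_b <- scielab_lab(eq$b, geom, white = config$white, params = config$params)
  ics <- ics_map(lab_a, lab_b)
  si <- gradient_magnitude(eq$a, config$channel_policy)
  sj <- gradient_magnitude(eq$b, config$channel_policy)
  gms <- gms_map(si, sj, c = config$gms_c)
  res <- list(icsi = icsi(ics), gmsd = gmsd(gms))
  if (isTRUE(config$include_mean)) res$ics_mean <- mean(ics$values)
  if (isTRUE(config$keep_maps)) res$maps <- list(ics = ics, gms = gms)
  structure(res, class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("<metric_result> ICSI=%.6g, GMSD=%.6g\n", x$icsi, x$gmsd))
  invisible(x)
}
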