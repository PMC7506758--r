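# Spatial CIELAB: device RGB -> XYZ -> opponent channels -> viewing-distance
# dependent low-pass filtering -> XYZ -> CIELAB. The filtering step models
# the spatial contrast sensitivity of the human visual system: fine spatial
# detail, especially chromatic detail, is attenuated before color
# differences are measured, so a pattern that is only distinguishable at
# unresolvable spatial frequencies scores as a match.

# sRGB (IEC 61966-2-1) linear RGB -> XYZ, D65 white.
.SRGB_TO_XYZ <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)

#' D65 reference white (Y-normalized)
#' @return XYZ triple with Y = 1.
#' @export
white_d65 <- function() c(X = 0.95047, Y = 1.0, Z = 1.08883)

srgb_decode <- function(v) {
  ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
}

#' Default display characterization (sRGB)
#'
#' A display characterization is a list with `transfer` (the
#' electro-optical transfer function mapping encoded `[0,1]` values to
#' linear light) and `matrix` (3x3 linear RGB -> XYZ). Plug in a measured
#' characterization when the display is not sRGB.
#'
#' @return A characterization list.
#' @export
srgb_characterization <- function() {
  list(name = "sRGB", transfer = srgb_decode, matrix = .SRGB_TO_XYZ)
}

apply_pixel_matrix <- function(px, M) {
  d <- dim(px)
  flat <- matrix(px, ncol = 3L)
  out <- flat %*% t(M)
  array(out, dim = d)
}

#' Convert device RGB to CIE XYZ
#'
#' Applies the characterization's transfer function and 3x3 matrix
#' per pixel. With the default sRGB characterization, reference white
#' (1,1,1) maps to D65 with Y = 1.
#'
#' @param img A deviceRGB [raster_image] with values in `[0, 1]`.
#' @param characterization A display characterization such as
#'   [srgb_characterization()].
#' @return A [raster_image] in XYZ space.
#' @export
rgb_to_xyz <- function(img, characterization = srgb_characterization()) {
  assert_space(img, "deviceRGB")
  tol <- 1e-6
  if (any(img$pixels < -tol) || any(img$pixels > 1 + tol)) {
    stop("deviceRGB values outside [0, 1]; normalize before conversion")
  }
  linear <- characterization$transfer(clip01(img$pixels))
  raster_image(apply_pixel_matrix(linear, characterization$matrix),
               space = "XYZ", range = c(0, 1))
}

.OPP_DEFAULT <- matrix(c(
  0.279, 0.72, -0.107,
  -0.449, 0.29, -0.077,
  0.086, -0.59, 0.501
), nrow = 3, byrow = TRUE)

#' Convert XYZ to opponent channels (and back)
#'
#' Linear 3x3 decomposition of XYZ into one achromatic (O1) and two
#' chromatic (O2 red-green, O3 blue-yellow) channels, the basis in which
#' the HVS low-pass filters are applied. `opponent_to_xyz` inverts it;
#' the round trip is the identity to machine precision.
#'
#' @param img A [raster_image] in XYZ (or OPP for the inverse).
#' @param matrix 3x3 opponent matrix; default from the package parameter
#'   file.
#' @return A [raster_image] in OPP (or XYZ) space.
#' @export
xyz_to_opponent <- function(img, matrix = .OPP_DEFAULT) {
  assert_space(img, "XYZ")
  raster_image(apply_pixel_matrix(img$pixels, matrix), space = "OPP",
               range = c(-1, 1))
}

#' @rdname xyz_to_opponent
#' @export
opponent_to_xyz <- function(img, matrix = .OPP_DEFAULT) {
  assert_space(img, "OPP")
  raster_image(apply_pixel_matrix(img$pixels, solve(matrix)), space = "XYZ",
               range = c(0, 1))
}

#' Read the spatial-filter parameter set
#'
#' Loads the opponent matrix and per-channel sums-of-Gaussians (weight,
#' spread in degrees) from a YAML document. The packaged defaults are the
#' published reference values of the spatial CIELAB filters.
#'
#' @param path Path to a parameter YAML; default is the packaged file.
#' @return A list with `opponent_matrix` (3x3) and `filters` (per-channel
#'   lists of weight/halfwidth_deg pairs).
#' @export
scielab_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "scielab-filters.yaml",
                        package = "camoscore", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  raw$opponent_matrix <- do.call(rbind, raw$opponent_matrix)
  raw
}

#' Realize the HVS low-pass kernels at a viewing geometry
#'
#' Each opponent channel's filter is a weighted sum of Gaussians specified
#' in degrees of visual angle; at `spd` samples per degree each term becomes
#' a discrete Gaussian of sigma `halfwidth_deg * spd` pixels, truncated at
#' three sigma (minimum 3x3 support), and the summed kernel is renormalized
#' to unit sum so uniform fields pass through unchanged.
#'
#' @param spd Samples per degree (> 0).
#' @param params Parameter list from [scielab_params()].
#' @return An object of class `opponent_kernels`: per channel, the term
#'   list (with realized 1-D kernels) and the realized 2-D kernel.
#' @export
build_kernels <- function(spd, params = scielab_params()) {
  if (spd <= 0) stop("spd must be positive")
  channels <- lapply(params$filters, function(terms) {
    terms <- lapply(terms, function(t) {
      sigma <- t$halfwidth_deg * spd
      c(t, list(sigma_px = sigma, k1d = gaussian_kernel_1d(sigma)))
    })
    wsum <- sum(vapply(terms, function(t) t$weight, 0))
    if (abs(wsum) < 1e-12) stop("filter weights sum to zero; cannot normalize")
    support <- max(vapply(terms, function(t) length(t$k1d), 0L))
    k2d <- matrix(0, support, support)
    for (t in terms) {
      pad <- (support - length(t$k1d)) %/% 2L
      k <- c(rep(0, pad), t$k1d, rep(0, pad))
      k2d <- k2d + t$weight * outer(k, k)
    }
    list(terms = terms, weight_sum = wsum, kernel2d = k2d / sum(k2d))
  })
  structure(list(spd = spd, channels = channels), class = "opponent_kernels")
}

# Filter one channel plane with its sum-of-Gaussians kernel, separably:
# identical to 2-D convolution with the renormalized kernel because the
# reflect-padded convolution is linear in the kernel.
filter_channel <- function(x, channel) {
  acc <- 0
  for (t in channel$terms) {
    acc <- acc + t$weight * conv_separable(x, t$k1d)
  }
  acc / channel$weight_sum
}

lab_f <- function(t) {
  delta <- 6 / 29
  ifelse(t > delta^3, t^(1 / 3), t / (3 * delta^2) + 4 / 29)
}

#' Convert XYZ to CIELAB
#'
#' Standard CIE 1976 L*a*b* with the given reference white
#' (Y-normalized).
#'
#' @param img A [raster_image] in XYZ space; negative values (possible
#'   after opponent filtering) are clipped to 0.
#' @param white XYZ triple of the reference white.
#' @return A `lab_image`: list with `pixels` (`H x W x 3` of L*, a*, b*)
#'   and `white`.
#' @export
xyz_to_lab <- function(img, white = white_d65()) {
  assert_space(img, "XYZ")
  px <- pmax(img$pixels, 0)
  fx <- lab_f(px[, , 1L] / white[1L])
  fy <- lab_f(px[, , 2L] / white[2L])
  fz <- lab_f(px[, , 3L] / white[3L])
  out <- array(0, dim(px))
  out[, , 1L] <- 116 * fy - 16
  out[, , 2L] <- 500 * (fx - fy)
  out[, , 3L] <- 200 * (fy - fz)
  structure(list(pixels = out, white = unname(white), space = "LAB"),
            class = "lab_image")
}

#' @export
dim.lab_image <- function(x) dim(x$pixels)

#' @export
print.lab_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<lab_image> %dx%d, L* range [%.2f, %.2f]\n", d[1L], d[2L],
              min(x$pixels[, , 1L]), max(x$pixels[, , 1L])))
  invisible(x)
}

#' Plain CIELAB of a device-RGB image (no spatial filtering)
#'
#' @inheritParams scielab_lab
#' @return A `lab_image`.
#' @export
lab_from_rgb <- function(img, white = white_d65(),
                         characterization = srgb_characterization()) {
  xyz_to_lab(rgb_to_xyz(img, characterization), white)
}

#' Spatial CIELAB transform
#'
#' Full pipeline: device RGB -> XYZ -> opponent channels -> per-channel
#' convolution with the HVS low-pass kernels realized at the viewing
#' geometry (symmetric boundary padding) -> XYZ -> CIELAB. Because the
#' kernels are unit-sum, a uniform image is left at its plain CIELAB value.
#'
#' @param img A deviceRGB [raster_image].
#' @param geom A [viewing_geometry()]; default 35 samples per degree.
#' @param white Reference white XYZ triple.
#' @param params Filter parameters from [scielab_params()].
#' @param characterization Display characterization; default sRGB.
#' @return A `lab_image`.
#' @examples
#' img <- raster_image(array(0.4, c(8, 8, 3)))
#' lab <- scielab_lab(img, viewing_geometry(spd = 35))
#' lab$pixels[1, 1, ]
#' @export
scielab_lab <- function(img, geom = viewing_geometry(spd = 35),
                        white = white_d65(), params = scielab_params(),
                        characterization = srgb_characterization()) {
  spd <- samples_per_degree(geom)
  kernels <- build_kernels(spd, params)
  opp <- xyz_to_opponent(rgb_to_xyz(img, characterization),
                         matrix = params$opponent_matrix)
  filtered <- opp$pixels
  names(kernels$channels) <- NULL
  for (c in 1:3) {
    filtered[, , c] <- filter_channel(opp$pixels[, , c], kernels$channels[[c]])
  }
  xyz <- opponent_to_xyz(raster_image(filtered, "OPP", c(-1, 1)),
                         matrix = params$opponent_matrix)
  xyz_to_lab(xyz, white)
}
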