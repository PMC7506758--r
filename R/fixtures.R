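# Seeded synthetic stimuli: uniform base colors overlaid with smoothed
# Gaussian noise, giving controllable color and texture structure so both
# metrics are exercised without any external image data.

# Run expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Specify a synthetic camouflage/background fixture
#'
#' @param seed Integer RNG seed; the same spec always produces bit-identical
#'   images. The background uses sub-seed `seed + 1000003`.
#' @param patch_size Integer `(height, width)` of the camouflage patch in
#'   pixels; defaults to the 100 x 300 patch geometry of the reference
#'   psychophysics setup.
#' @param background_size Integer `(height, width)` of the background;
#'   default 270 x 480 keeps the 16:9 display aspect at desk scale.
#' @param base_color RGB triple in `[0, 1]`.
#' @param noise_amplitude Standard deviation of the added texture noise in
#'   `[0, 1]` units; 0 gives an exactly uniform image.
#' @param smoothing_sigma_px Gaussian blur sigma (pixels) applied to the
#'   noise field, setting the spatial scale of the texture.
#' @return An object of class `fixture_spec`.
#' @seealso [generate_fixture()]
#' @export
fixture_spec <- function(seed, patch_size = c(100, 300),
                         background_size = c(270, 480),
                         base_color = c(0.5, 0.5, 0.5),
                         noise_amplitude = 0.1, smoothing_sigma_px = 2) {
  if (any(patch_size < 3) || any(background_size < 3)) {
    stop("fixture dimensions must be at least 3x3")
  }
  if (noise_amplitude < 0) stop("noise_amplitude must be >= 0")
  if (smoothing_sigma_px < 0) stop("smoothing_sigma_px must be >= 0")
  if (length(base_color) != 3 || any(base_color < 0 | base_color > 1)) {
    stop("base_color must be an RGB triple in [0, 1]")
  }
  structure(list(seed = as.integer(seed),
                 patch_size = as.integer(patch_size),
                 background_size = as.integer(background_size),
                 base_color = as.numeric(base_color),
                 noise_amplitude = noise_amplitude,
                 smoothing_sigma_px = smoothing_sigma_px),
            class = "fixture_spec")
}

# One textured plane set: base color + seeded smoothed unit-sd noise.
textured_image <- function(seed, h, w, base_color, amplitude, sigma) {
  px <- array(rep(base_color, each = h * w), dim = c(h, w, 3L))
  if (amplitude > 0) {
    noise <- with_seed(seed, {
      lapply(1:3, function(i) matrix(stats::rnorm(h * w), h, w))
    })
    for (c in 1:3) {
      n <- gaussian_smooth(noise[[c]], sigma)
      s <- sqrt(mean((n - mean(n))^2))
      if (s > 0) n <- (n - mean(n)) / s
      px[, , c] <- px[, , c] + amplitude * n
    }
    px <- clip01(px)
  }
  raster_image(px, space = "deviceRGB", range = c(0, 1))
}

#' Generate a seeded synthetic patch/background pair
#'
#' @param spec A [fixture_spec()].
#' @return List with elements `patch` and `background`, both
#'   [raster_image] objects in deviceRGB.
#' @examples
#' fx <- generate_fixture(fixture_spec(seed = 7, patch_size = c(16, 16),
#'                                     background_size = c(16, 16)))
#' range(fx$patch$pixels)
#' @export
generate_fixture <- function(spec) {
  if (!inherits(spec, "fixture_spec")) stop("expected a fixture_spec")
  patch <- textured_image(spec$seed, spec$patch_size[1L], spec$patch_size[2L],
                          spec$base_color, spec$noise_amplitude,
                          spec$smoothing_sigma_px)
  background <- textured_image(spec$seed + 1000003L,
                               spec$background_size[1L],
                               spec$background_size[2L],
                               spec$base_color, spec$noise_amplitude,
                               spec$smoothing_sigma_px)
  list(patch = patch, background = background)
}

#' Add seeded smoothed noise to an existing image
#'
#' Produces camouflage variants of graded fidelity from a background: with
#' `amplitude = 0` the input is returned unchanged, and increasing amplitudes
#' degrade the background match progressively.
#'
#' @param img A deviceRGB [raster_image].
#' @param amplitude Noise standard deviation in `[0, 1]` units.
#' @param smoothing_sigma_px Gaussian blur sigma (pixels) for the noise field.
#' @param seed Integer RNG seed.
#' @return A deviceRGB [raster_image] of the same dimensions.
#' @export
perturb_image <- function(img, amplitude, smoothing_sigma_px = 2, seed = 1) {
  assert_space(img, "deviceRGB")
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (amplitude == 0) return(img)
  d <- dim(img$pixels)
  noise <- with_seed(seed, {
    lapply(1:3, function(i) matrix(stats::rnorm(d[1L] * d[2L]), d[1L], d[2L]))
  })
  px <- img$pixels
  for (c in 1:3) {
    n <- gaussian_smooth(noise[[c]], smoothing_sigma_px)
    s <- sqrt(mean((n - mean(n))^2))
    if (s > 0) n <- (n - mean(n)) / s
    px[, , c] <- px[, , c] + amplitude * n
  }
  raster_image(clip01(px), space = "deviceRGB", range = c(0, 1))
}

#' Canonical six-pattern, three-background fixture experiment
#'
#' Builds the package's standard synthetic study: six camouflage patches
#' (woodland, multicam, marpat, desert, navy, urban palettes) at the given
#' patch size and three sea-like backgrounds (calm, sparkling, rough) that
#' share an ocean base color but differ in texture amplitude and scale.
#'
#' @param seed Integer RNG seed controlling all textures.
#' @param patch_size `(height, width)` of each camouflage patch.
#' @param background_size `(height, width)` of each background.
#' @return List with named lists `camos` (6) and `backgrounds` (3) of
#'   deviceRGB [raster_image] objects.
#' @export
canonical_fixture_set <- function(seed = 1, patch_size = c(100, 300),
                                  background_size = c(270, 480)) {
  camo_defs <- list(
    woodland = list(color = c(0.25, 0.32, 0.18), amp = 0.12, sigma = 3),
    multicam = list(color = c(0.55, 0.47, 0.33), amp = 0.10, sigma = 4),
    marpat   = list(color = c(0.30, 0.33, 0.22), amp = 0.14, sigma = 2),
    desert   = list(color = c(0.70, 0.60, 0.45), amp = 0.08, sigma = 5),
    navy     = list(color = c(0.22, 0.28, 0.38), amp = 0.10, sigma = 3),
    urban    = list(color = c(0.50, 0.50, 0.52), amp = 0.09, sigma = 2)
  )
  sea <- c(0.20, 0.33, 0.45)
  bg_defs <- list(
    sea_calm      = list(color = sea, amp = 0.04, sigma = 6),
    sea_sparkling = list(color = sea, amp = 0.12, sigma = 2),
    sea_rough     = list(color = sea, amp = 0.18, sigma = 4)
  )
  camos <- lapply(seq_along(camo_defs), function(i) {
    d <- camo_defs[[i]]
    textured_image(seed + 13L * i, patch_size[1L], patch_size[2L],
                   d$color, d$amp, d$sigma)
  })
  names(camos) <- names(camo_defs)
  backgrounds <- lapply(seq_along(bg_defs), function(j) {
    d <- bg_defs[[j]]
    textured_image(seed + 101L * j + 500L, background_size[1L],
                   background_size[2L], d$color, d$amp, d$sigma)
  })
  names(backgrounds) <- names(bg_defs)
  list(camos = camos, backgrounds = backgrounds)
}
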