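test_that("load_image normalizes, replicates grayscale and drops alpha", {
  tmp <- withr::local_tempdir()
  # 8-bit color PNG round-trips bit-exactly through save_image/load_image
  px <- array(sample(0:255, 6 * 5 * 3, replace = TRUE) / 255, c(6, 5, 3))
  px[1, 1, 1] <- 1 # full-scale 8-bit code maps to channel value 1.0
  p <- file.path(tmp, "a.png")
  save_image(raster_image(px), p)
  back <- load_image(p)
  expect_identical(back$pixels, px)
  expect_equal(back$pixels[1, 1, 1], 1.0)

  # grayscale replicated onto three identical channels
  g <- file.path(tmp, "g.png")
  png::writePNG(matrix(runif(20), 4, 5), g)
  gi <- load_image(g)
  expect_identical(gi$pixels[, , 1], gi$pixels[, , 2])
  expect_identical(gi$pixels[, , 1], gi$pixels[, , 3])

  # alpha dropped
  a <- file.path(tmp, "rgba.png")
  png::writePNG(array(runif(4 * 4 * 4), c(4, 4, 4)), a)
  expect_equal(dim(load_image(a))[3], 3)

  # a text file with a .png name is a decode error naming the path
  bad <- file.path(tmp, "fake.png")
  writeLines("not an image", bad)
  expect_error(load_image(bad), "fake.png")
  expect_error(load_image(file.path(tmp, "absent.png")), "does not exist")
})

test_that("equalize_resolution honours crop and resize policies and is idempotent", {
  a <- rand_rgb(10, 10, 1)
  b <- rand_rgb(20, 20, 2)

  same <- equalize_resolution(a, rand_rgb(10, 10, 3))
  expect_identical(dim(same$a), c(10L, 10L, 3L))
  expect_identical(same$a$pixels, a$pixels)

  cr <- equalize_resolution(a, b, policy = "crop")
  expect_identical(dim(cr$a)[1:2], c(10L, 10L))
  expect_identical(dim(cr$b)[1:2], c(10L, 10L))
  # centered region of the larger image
  expect_identical(cr$b$pixels, b$pixels[6:15, 6:15, ])

  rs <- equalize_resolution(a, b, policy = "resize")
  expect_identical(rs$a$pixels, a$pixels)
  expect_identical(dim(rs$b)[1:2], c(10L, 10L))

  # idempotence: a second application changes nothing
  again <- equalize_resolution(rs$a, rs$b, policy = "resize")
  expect_identical(again$b$pixels, rs$b$pixels)

  expect_error(equalize_resolution(a, xyz_to_opponent(rgb_to_xyz(b))),
               "same color space")
})

test_that("bicubic resize preserves constants and reproduces identity", {
  flat <- raster_image(array(0.37, c(9, 9, 3)))
  out <- equalize_resolution(rand_rgb(5, 7, 4), flat)$b
  expect_equal(max(abs(out$pixels - 0.37)), 0, tolerance = 1e-12)
})

test_that("samples_per_degree follows the small-angle formula", {
  g <- viewing_geometry(distance_mm = 550, pixel_pitch_mm = 0.2747)
  expect_equal(samples_per_degree(g), 34.94, tolerance = 1e-3)
  # pitch numerically equal to (pi/180)*distance gives exactly 1 spd
  d <- 431
  g1 <- viewing_geometry(distance_mm = d, pixel_pitch_mm = (pi / 180) * d)
  expect_equal(samples_per_degree(g1), 1.0, tolerance = 1e-12)
  # strictly increasing in distance, strictly decreasing in pitch
  spd <- function(dist, pitch) {
    samples_per_degree(viewing_geometry(distance_mm = dist,
                                        pixel_pitch_mm = pitch))
  }
  expect_equal(spd(1100, 0.2747), 2 * spd(550, 0.2747))
  dists <- seq(100, 1000, by = 100)
  expect_true(all(diff(sapply(dists, spd, pitch = 0.25)) > 0))
  pitches <- seq(0.1, 0.5, by = 0.05)
  expect_true(all(diff(sapply(pitches, spd, dist = 550)) < 0))
  expect_error(viewing_geometry(distance_mm = -1, pixel_pitch_mm = 0.25),
               "positive")
  expect_error(viewing_geometry(spd = 0), "positive")
})

test_that("fixture generator is seeded, bounded and honours the no-noise case", {
  spec <- fixture_spec(seed = 11, patch_size = c(100, 300),
                       background_size = c(32, 48),
                       base_color = c(0.3, 0.5, 0.7),
                       noise_amplitude = 0.15, smoothing_sigma_px = 2)
  fx1 <- generate_fixture(spec)
  fx2 <- generate_fixture(spec)
  expect_identical(fx1$patch$pixels, fx2$patch$pixels)
  expect_identical(fx1$background$pixels, fx2$background$pixels)
  # patch_size is (height, width): the 300x100 display patch is H=100, W=300
  expect_identical(dim(fx1$patch)[1:2], c(100L, 300L))
  expect_true(all(fx1$patch$pixels >= 0 & fx1$patch$pixels <= 1))
  expect_true(all(fx1$background$pixels >= 0 & fx1$background$pixels <= 1))
  # patch and background textures differ (independent sub-seeds)
  expect_gt(mean(abs(fx1$patch$pixels[1:32, 1:48, ] -
                     fx1$background$pixels)), 0)

  quiet <- generate_fixture(fixture_spec(seed = 11, patch_size = c(8, 8),
                                         background_size = c(8, 8),
                                         base_color = c(0.2, 0.4, 0.6),
                                         noise_amplitude = 0))
  expect_identical(unique(as.vector(quiet$patch$pixels[, , 1])), 0.2)
  expect_identical(unique(as.vector(quiet$patch$pixels[, , 3])), 0.6)

  expect_error(fixture_spec(seed = 1, patch_size = c(2, 10)), "3x3")
})

test_that("perturb_image at amplitude zero is the identity", {
  img <- rand_rgb(12, 12, 5)
  expect_identical(perturb_image(img, 0, seed = 9)$pixels, img$pixels)
  p1 <- perturb_image(img, 0.1, seed = 9)
  p2 <- perturb_image(img, 0.1, seed = 9)
  expect_identical(p1$pixels, p2$pixels)
  expect_gt(mean(abs(p1$pixels - img$pixels)), 0)
})
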