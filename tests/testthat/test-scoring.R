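rand_matrix <- function(M, N, seed) {
  set.seed(seed)
  x <- array(runif(M * N * 2, 0.01, 2), c(M, N, 2),
             dimnames = list(paste0("camo", 1:M), paste0("bg", 1:N),
                             c("icsi", "gmsd")))
  camoscore:::new_difference_matrix(x, paste0("camo", 1:M),
                                    paste0("bg", 1:N))
}

test_that("difference matrix has the M x N x 2 contract", {
  set.seed(1)
  camos <- lapply(1:2, function(i) rand_rgb(12, 12, i))
  bgs <- lapply(1:3, function(j) rand_rgb(12, 12, 10 + j))
  camos[[1]] <- bgs[[1]] # identity pair at (1, 1)
  x <- build_difference_matrix(camos, bgs)
  expect_identical(dim(x$x), c(2L, 3L, 2L))
  expect_identical(x$metric_ids, c("icsi", "gmsd"))
  expect_true(all(x$x >= 0))
  expect_equal(unname(x$x[1, 1, ]), c(0, 0))
  expect_error(build_difference_matrix(list(), bgs), "at least one")
})

test_that("entropy weights follow the proportion-entropy definition", {
  # identical value distributions across the two metrics: equal weights
  set.seed(2)
  vals <- matrix(runif(12, 0.1, 1), 3, 4)
  sym <- camoscore:::new_difference_matrix(
    array(c(vals, vals), c(3, 4, 2)), paste0("c", 1:3), paste0("b", 1:4))
  expect_equal(unname(entropy_weights(sym)), c(0.5, 0.5))

  # constant slice (uniform proportions, e = 1) gets weight 0
  const_icsi <- camoscore:::new_difference_matrix(
    array(c(rep(2, 12), runif(12)), c(3, 4, 2)),
    paste0("c", 1:3), paste0("b", 1:4))
  w <- entropy_weights(const_icsi)
  expect_equal(unname(w), c(0, 1))

  # all-zero slice handled by the same degenerate rule
  zero_icsi <- camoscore:::new_difference_matrix(
    array(c(rep(0, 12), runif(12)), c(3, 4, 2)),
    paste0("c", 1:3), paste0("b", 1:4))
  expect_equal(unname(entropy_weights(zero_icsi)), c(0, 1))

  # both metrics uniform: equal weights with a warning
  flat <- camoscore:::new_difference_matrix(
    array(c(rep(1, 12), rep(3, 12)), c(3, 4, 2)),
    paste0("c", 1:3), paste0("b", 1:4))
  expect_warning(wf <- entropy_weights(flat), "equal weights")
  expect_equal(unname(wf), c(0.5, 0.5))
})

test_that("entropy weights match the naive oracle and its invariances", {
  for (seed in 1:10) {
    x <- rand_matrix(sample(2:6, 1), sample(2:6, 1), seed)
    w <- entropy_weights(x)
    expect_equal(unname(w), naive_entropy_weights(x$x), tolerance = 1e-12)
    expect_true(all(w >= 0 & w <= 1))
    expect_lt(abs(sum(w) - 1), 1e-12)

    # invariant to permuting cells within a metric
    perm <- x
    d <- dim(x$x)
    for (k in 1:2) {
      set.seed(seed + 50)
      slice <- x$x[, , k]
      perm$x[, , k] <- matrix(sample(slice), d[1], d[2])
    }
    expect_equal(entropy_weights(perm), w, tolerance = 1e-12)

    # invariant to positive rescaling of one metric slice
    scaled <- x
    scaled$x[, , 1] <- scaled$x[, , 1] * 37.5
    expect_equal(entropy_weights(scaled), w, tolerance = 1e-12)
  }
})

test_that("aggregate_scores computes the weighted mean with correct polarity", {
  one <- camoscore:::new_difference_matrix(
    array(c(2, 4), c(1, 1, 2)), "c1", "b1")
  r <- aggregate_scores(one, w = c(0.5, 0.5))
  expect_equal(r$score, 3)

  x <- rand_matrix(4, 3, 3)
  # degenerate weight: score equals the mean ICSI alone
  r_icsi <- aggregate_scores(x, w = c(1, 0))
  expect_equal(r_icsi$score, unname(apply(x$x[, , 1], 1, mean)))
  # literal transposed orientation scores backgrounds
  r_bg <- aggregate_scores(x, w = c(0.5, 0.5), orientation = "per_background")
  expect_identical(nrow(r_bg), 3L)
  expect_equal(r_bg$score,
               unname(0.5 * colMeans(x$x[, , 1]) + 0.5 * colMeans(x$x[, , 2])))

  # all-zero matrix: all scores 0, ties ranked in input order
  zero <- camoscore:::new_difference_matrix(
    array(0, c(3, 2, 2)), paste0("c", 1:3), paste0("b", 1:2))
  expect_warning(rz <- aggregate_scores(zero), "equal weights")
  expect_equal(rz$score, rep(0, 3))
  expect_identical(rz$rank, 1:3)

  expect_error(aggregate_scores(x, w = c(1, 0, 0)), "does not match")

  # monotone: increasing one cell never decreases that pattern's score
  w <- entropy_weights(x)
  bumped <- x
  bumped$x[2, 1, 1] <- bumped$x[2, 1, 1] + 1
  expect_gte(aggregate_scores(bumped, w)$score[2],
             aggregate_scores(x, w)$score[2])
})

test_that("absolute Pearson correlation has the documented conventions", {
  expect_equal(pearson_abs(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(pearson_abs(c(1, 2, 3), c(-2, -4, -6)), 1.0)
  expect_equal(pearson_abs(c(1, 2, 3), c(1, 2, 4)), 0.982, tolerance = 1e-3)
  expect_error(pearson_abs(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_abs(c(1, 2), c(1, 2)), "at least 3")
})

test_that("correlations against a subjective table are matched by pattern id", {
  x <- rand_matrix(4, 3, 9)
  report <- aggregate_scores(x)
  subj <- data.frame(pattern_id = rev(report$pattern_id),
                     hit_rate = c(80, 60, 40, 20),
                     detection_time = c(1, 2, 3, 4))
  rho <- correlate_with_subjective(report, subj)
  expect_named(rho, c("hit_rate", "detection_time"))
  expect_true(all(rho >= 0 & rho <= 1))
  expect_error(correlate_with_subjective(report,
                                         data.frame(pattern_id = "zz",
                                                    hit_rate = 1)),
               "missing patterns")
})

test_that("a persisted difference matrix reloads and rescores identically", {
  x <- rand_matrix(5, 4, 21)
  path <- tempfile(fileext = ".csv")
  write_difference_matrix(x, path)
  back <- read_difference_matrix(path)
  expect_equal(back$x, x$x, tolerance = 1e-12)
  expect_identical(back$camo_ids, x$camo_ids)
  r1 <- aggregate_scores(x)
  r2 <- aggregate_scores(back)
  expect_equal(r2$score, r1$score, tolerance = 1e-12)
  expect_identical(r2$rank, r1$rank)
})
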