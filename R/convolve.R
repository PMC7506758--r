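# Reflect-padded convolution and bicubic resampling primitives.
#
# All spatial filtering in the package (HVS opponent-channel low-pass
# filters, Sobel gradients, fixture smoothing) goes through these helpers so
# that boundary handling is uniform: symmetric (mirror) padding, the scheme
# that avoids dark-edge artifacts on unit-sum low-pass kernels.

# Map an out-of-range index onto [1, n] by symmetric reflection
# (... 2 1 | 1 2 ... n | n ... ), period 2n, so kernels longer than the
# image remain well defined.
reflect_index <- function(j, n) {
  jj <- (j - 1L) %% (2L * n)
  ifelse(jj < n, jj + 1L, 2L * n - jj)
}

# Dense n x n operator applying a centered odd-length 1-D kernel with
# symmetric padding folded into the matrix. Row sums equal sum(kernel)
# exactly, so unit-sum kernels preserve constants to machine precision.
conv_matrix_1d <- function(n, kernel) {
  len <- length(kernel)
  if (len %% 2L != 1L) stop("kernel length must be odd")
  r <- (len - 1L) %/% 2L
  A <- matrix(0, n, n)
  i <- seq_len(n)
  for (t in seq.int(-r, r)) {
    idx <- reflect_index(i + t, n)
    cells <- cbind(i, idx)
    A[cells] <- A[cells] + kernel[t + r + 1L]
  }
  A
}

# Separable convolution of a matrix with an outer(k, k) kernel:
# filter down columns with k, then along rows with k.
conv_separable <- function(x, kernel1d) {
  A <- conv_matrix_1d(nrow(x), kernel1d)
  B <- conv_matrix_1d(ncol(x), kernel1d)
  A %*% x %*% t(B)
}

# Unit-sum discrete Gaussian, support truncated at +/- 3 sigma
# (never below a 3-tap kernel, keeping Sobel-compatible minimum support).
gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(c(0, 1, 0))
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- seq.int(-r, r)
  g <- exp(-(x^2) / (2 * sigma^2))
  g / sum(g)
}

gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  conv_separable(x, gaussian_kernel_1d(sigma))
}

pad_symmetric <- function(x, r) {
  ri <- reflect_index(seq.int(1L - r, nrow(x) + r), nrow(x))
  ci <- reflect_index(seq.int(1L - r, ncol(x) + r), ncol(x))
  x[ri, ci, drop = FALSE]
}

# True 2-D convolution (kernel flipped) with a 3x3 kernel, symmetric padding.
conv2d_3x3 <- function(x, kernel) {
  stopifnot(all(dim(kernel) == c(3L, 3L)))
  if (nrow(x) < 3L || ncol(x) < 3L) stop("image must be at least 3x3")
  kf <- kernel[3:1, 3:1]
  p <- pad_symmetric(x, 1L)
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  for (a in 0:2) {
    for (b in 0:2) {
      out <- out + kf[a + 1L, b + 1L] * p[a + seq_len(h), b + seq_len(w)]
    }
  }
  out
}

# Keys cubic interpolation kernel (a = -0.5); partitions unity at any phase.
keys_cubic <- function(x) {
  a <- -0.5
  x <- abs(x)
  w <- numeric(length(x))
  near <- x <= 1
  mid <- x > 1 & x < 2
  w[near] <- (a + 2) * x[near]^3 - (a + 3) * x[near]^2 + 1
  w[mid] <- a * x[mid]^3 - 5 * a * x[mid]^2 + 8 * a * x[mid] - 4 * a
  w
}

# n_out x n_in bicubic resampling operator, pixel centers aligned,
# edge samples clamped (replicated).
resample_matrix <- function(n_out, n_in) {
  A <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * scale + 0.5
    base <- floor(src)
    taps <- (base - 1):(base + 2)
    w <- keys_cubic(src - taps)
    taps <- pmin(pmax(taps, 1L), n_in)
    for (t in seq_along(taps)) A[i, taps[t]] <- A[i, taps[t]] + w[t]
  }
  A
}

resize_bicubic_plane <- function(x, out_h, out_w) {
  R <- resample_matrix(out_h, nrow(x))
  C <- resample_matrix(out_w, ncol(x))
  R %*% x %*% t(C)
}
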