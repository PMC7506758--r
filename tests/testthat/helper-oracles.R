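# Independent brute-force reference implementations used as oracles.
# Deliberately written as plain per-pixel loops over the defining formulas,
# sharing no code with the package's vectorized paths.

rand_rgb <- function(h, w, seed) {
  set.seed(seed)
  raster_image(array(runif(h * w * 3), c(h, w, 3)))
}

naive_pop_sd <- function(x) {
  x <- as.vector(x)
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / length(x))
}

naive_ics <- function(la, lb) {
  d <- dim(la)[1:2]
  out <- matrix(0, d[1], d[2])
  for (u in seq_len(d[1])) {
    for (v in seq_len(d[2])) {
      out[u, v] <- sqrt((la[u, v, 1] - lb[u, v, 1])^2 +
                        (la[u, v, 2] - lb[u, v, 2])^2 +
                        (la[u, v, 3] - lb[u, v, 3])^2)
    }
  }
  out
}

naive_gms <- function(si, sj, c) {
  out <- matrix(0, nrow(si), ncol(si))
  for (u in seq_len(nrow(si))) {
    for (v in seq_len(ncol(si))) {
      out[u, v] <- (2 * si[u, v] * sj[u, v] + c) /
        (si[u, v]^2 + sj[u, v]^2 + c)
    }
  }
  out
}

# scipy-style symmetric reflection of a single index
naive_reflect <- function(j, n) {
  while (j < 1 || j > n) {
    if (j < 1) j <- 1 - j
    if (j > n) j <- 2 * n + 1 - j
  }
  j
}

# True convolution (kernel flipped) of a 3x3 kernel, symmetric padding.
naive_sobel_magnitude <- function(plane) {
  sh <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  sv <- t(sh)
  h <- nrow(plane); w <- ncol(plane)
  out <- matrix(0, h, w)
  for (u in seq_len(h)) {
    for (v in seq_len(w)) {
      gh <- 0; gv <- 0
      for (a in -1:1) {
        for (b in -1:1) {
          px <- plane[naive_reflect(u - a, h), naive_reflect(v - b, w)]
          gh <- gh + sh[a + 2, b + 2] * px
          gv <- gv + sv[a + 2, b + 2] * px
        }
      }
      out[u, v] <- sqrt(gh^2 + gv^2)
    }
  }
  out
}

# Per-pixel CIE 1976 L*a*b* from XYZ, straight from the defining formulas.
naive_lab <- function(xyz, white) {
  f <- function(t) {
    if (t > (6 / 29)^3) t^(1 / 3) else t / (3 * (6 / 29)^2) + 4 / 29
  }
  d <- dim(xyz)
  out <- array(0, d)
  for (u in seq_len(d[1])) {
    for (v in seq_len(d[2])) {
      fx <- f(max(xyz[u, v, 1], 0) / white[1])
      fy <- f(max(xyz[u, v, 2], 0) / white[2])
      fz <- f(max(xyz[u, v, 3], 0) / white[3])
      out[u, v, 1] <- 116 * fy - 16
      out[u, v, 2] <- 500 * (fx - fy)
      out[u, v, 3] <- 200 * (fy - fz)
    }
  }
  out
}

# Entropy weights evaluated cell by cell from the defining sums.
naive_entropy_weights <- function(x) {
  d <- dim(x)
  dk <- numeric(d[3])
  for (k in seq_len(d[3])) {
    total <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) total <- total + x[i, j, k]
    if (total <= 0) { dk[k] <- 0; next }
    s <- 0
    for (i in seq_len(d[1])) {
      for (j in seq_len(d[2])) {
        p <- x[i, j, k] / total
        if (p > 0) s <- s + p * log(p)
      }
    }
    e <- -s / log(d[1] * d[2])
    dk[k] <- 1 - e
  }
  if (sum(dk) <= 0) rep(1 / d[3], d[3]) else dk / sum(dk)
}
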