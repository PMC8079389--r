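# Shared fixture builders; everything is generated in code at test time.

# Small-geometry generator config for fast tests.
small_cfg <- function(...) {
  spont_config(fov = c(40L, 64L), hemi_semiaxes = c(15, 12),
               hemi_col_center = 16, ...)
}

# A smooth textured frame (sum of random Gaussian blobs), reproducible.
textured_frame <- function(nr = 48, nc = 64, n_blobs = 6, seed = 1) {
  set.seed(seed)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  f <- matrix(0, nr, nc)
  for (k in seq_len(n_blobs)) {
    f <- f + runif(1, 50, 100) *
      exp(-((rows - runif(1, 0.2 * nr, 0.8 * nr))^2 +
              (cols - runif(1, 0.2 * nc, 0.8 * nc))^2) / (2 * 16))
  }
  f
}

# Mask the movie (NA outside the ROI) without pooling; keeps the generator
# geometry so line-scan bins align with generator coordinates.
mask_movie <- function(movie, masks) {
  movie$data[!(masks$left | masks$right)] <- NA_real_
  movie
}

# Direct 2-D convolution oracle (zero padding), independent of the package's
# filtering path.
conv2_oracle <- function(x, k) {
  nr <- nrow(x); nc <- ncol(x)
  hr <- (nrow(k) - 1L) %/% 2L; hc <- (ncol(k) - 1L) %/% 2L
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (a in -hr:hr) for (b in -hc:hc) {
      ii <- i + a; jj <- j + b
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
        acc <- acc + x[ii, jj] * k[hr + 1L + a, hc + 1L + b]
    }
    out[i, j] <- acc
  }
  out
}

# Sort-based percentile oracle: linear interpolation between order
# statistics (the convention the package declares).
percentile_oracle <- function(v, p) {
  s <- sort(v)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Residual-regression partial-correlation oracle.
partial_cor_oracle <- function(x, y, z) {
  rx <- residuals(lm(x ~ z))
  ry <- residuals(lm(y ~ z))
  cor(rx, ry)
}

expect_step_error <- function(expr) {
  expect_error(expr, "already been applied")
}
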