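test_that("photobleach correction handles constant, short and decaying input", {
  const <- movie_stack(array(5, c(6, 6, 50)))
  expect_warning(res <- correct_photobleach(const), "degenerate")
  expect_identical(res$movie$data, const$data)
  expect_true(res$fit$degenerate)

  short <- movie_stack(array(1, c(4, 4, 5)))
  expect_error(correct_photobleach(short), "at least 10 frames")

  m <- movie_stack(array(rep(80, 10 * 10 * 300), c(10, 10, 300)))
  fac <- exp(-(0:299) / 200)
  m$data <- m$data * rep(fac, each = 100)
  res <- correct_photobleach(m)
  expect_equal(res$fit$tau_frames, 200, tolerance = 0.05)
  mu <- apply(res$movie$data, 3, mean)
  expect_lt(diff(range(mu)) / mu[1], 0.01)
})

test_that("registration of a static movie returns zero shifts, no flags", {
  fr <- textured_frame(32, 32, seed = 2)
  m <- movie_stack(array(rep(fr, 10), c(32, 32, 10)))
  reg <- register_frames(m)
  expect_true(all(reg$motion$amplitude == 0))
  expect_false(any(reg$motion$corrupted))
})

test_that("a 0.4,0.4 px shift has amplitude ~0.57 and is flagged corrupted", {
  fr <- textured_frame(48, 48, seed = 3)
  arr <- array(rep(fr, 6), c(48, 48, 6))
  m <- movie_stack(arr)
  sh <- matrix(0, 6, 2); sh[4, ] <- c(0.4, 0.4)
  mv <- inject_artifacts(m, shifts = sh)
  reg <- register_frames(mv, reference = 1)
  expect_equal(reg$motion$amplitude[4], sqrt(0.32), tolerance = 0.1)
  expect_true(reg$motion$corrupted[4])
  expect_false(any(reg$motion$corrupted[-4]))
})

test_that("all-zero frames register with zero shift and a low-confidence flag", {
  arr <- array(0, c(16, 16, 4))
  arr[, , 1] <- textured_frame(16, 16, n_blobs = 2, seed = 4)
  reg <- register_frames(movie_stack(arr), reference = 1)
  expect_true(all(reg$motion$low_confidence[2:4]))
  expect_true(all(reg$motion$amplitude[2:4] == 0))
})

test_that("Gaussian smoothing matches the direct-convolution oracle", {
  const <- movie_stack(array(3, c(16, 16, 2)))
  expect_equal(smooth_frames(const)$data, const$data, tolerance = 1e-12)

  imp <- array(0, c(21, 21, 1)); imp[11, 11, 1] <- 1
  sm <- smooth_frames(movie_stack(imp), sigma = 1)
  k <- icbands:::gaussian_kernel(1)
  oracle <- conv2_oracle(imp[, , 1], k)
  expect_equal(sm$data[11, 11, 1], oracle[11, 11], tolerance = 1e-10)
  expect_equal(sm$data[, , 1], oracle, tolerance = 1e-10)

  interior <- array(0, c(24, 24, 1))
  interior[9:16, 9:16, 1] <- matrix(runif(64), 8, 8)
  sm2 <- smooth_frames(movie_stack(interior), sigma = 1)
  expect_equal(sum(sm2$data), sum(interior), tolerance = 1e-6)
})

test_that("masking and 2x2 pooling equal the block-mean oracle", {
  arr <- array(0, c(2, 2, 1)); arr[, , 1] <- matrix(1:4, 2, 2)
  m <- movie_stack(arr)
  masks <- roi_mask_set(matrix(TRUE, 2, 2), matrix(FALSE, 2, 2),
                        outside = matrix(FALSE, 2, 2))
  expect_equal(as.vector(mask_and_downsample(m, masks)$movie$data), 2.5)

  set.seed(8)
  arr <- array(runif(8 * 8 * 5), c(8, 8, 5))
  left <- matrix(FALSE, 8, 8); left[2:7, 1:4] <- TRUE
  right <- matrix(FALSE, 8, 8); right[2:7, 5:8] <- TRUE
  masks <- roi_mask_set(left, right)
  ds <- mask_and_downsample(movie_stack(arr), masks)$movie$data
  roi <- left | right
  oracle <- array(NA_real_, c(4, 4, 5))
  for (i in 1:4) for (j in 1:4) for (t in 1:5) {
    rr <- (2 * i - 1):(2 * i); cc <- (2 * j - 1):(2 * j)
    vals <- arr[rr, cc, t][roi[rr, cc]]
    if (length(vals)) oracle[i, j, t] <- mean(vals)
  }
  expect_equal(ds, oracle, tolerance = 1e-12)

  m1 <- movie_stack(array(1, c(8, 8, 3)))
  ds1 <- mask_and_downsample(m1, masks)
  expect_true(all(ds1$movie$data[!is.na(ds1$movie$data)] == 1))
})

test_that("odd trailing dimensions are dropped with a warning", {
  m <- movie_stack(array(1, c(5, 6, 2)))
  masks <- roi_mask_set(matrix(TRUE, 5, 6), matrix(FALSE, 5, 6),
                        outside = matrix(FALSE, 5, 6))
  expect_warning(out <- mask_and_downsample(m, masks), "odd")
  expect_equal(dim(out$movie$data)[1:2], c(2L, 3L))
})

test_that("SVD denoising obeys the Eckart-Young tail-energy bound", {
  set.seed(5)
  u <- runif(36); v <- runif(40)
  rank1 <- array(outer(matrix(u, 6, 6), v), c(6, 6, 40))
  m1 <- svd_denoise(movie_stack(rank1), k = 1)
  expect_lt(max(abs(m1$data - rank1)), 1e-8)

  X <- matrix(0, 36, 40)
  for (r in 1:3) X <- X + outer(rnorm(36), rnorm(40))
  X <- X + matrix(rnorm(36 * 40, sd = 0.05), 36, 40)
  arr <- array(X, c(6, 6, 40))
  den <- svd_denoise(movie_stack(arr), k = 3)
  sv <- svd(X)                           # dense SVD oracle
  tail_energy <- sqrt(sum(sv$d[4:length(sv$d)]^2))
  err <- sqrt(sum((den$data - arr)^2))
  expect_lte(err, tail_energy + 1e-8)

  full <- svd_denoise(movie_stack(arr), k = 36)
  expect_lt(max(abs(full$data - arr)), 1e-8)
  expect_warning(svd_denoise(movie_stack(rank1), k = 30), "rank")
})

test_that("dF/F0 uses the declared percentile convention", {
  const <- movie_stack(array(7, c(4, 4, 20)))
  expect_true(all(normalize_dff(const)$data == 0))

  set.seed(11)
  arr <- array(runif(4 * 4 * 100, 50, 150), c(4, 4, 100))
  dff <- normalize_dff(movie_stack(arr), f0_percentile = 5)
  for (px in list(c(1, 1), c(3, 4))) {
    v <- arr[px[1], px[2], ]
    f0 <- percentile_oracle(v, 0.05)
    expect_equal(dff$data[px[1], px[2], ], (v - f0) / f0, tolerance = 1e-12)
    # the trace value equal to F0 maps to 0
    expect_equal(min(abs(dff$data[px[1], px[2], ] -
                           (v - f0) / f0)), 0)
  }

  bad <- array(1, c(3, 3, 20)); bad[2, 2, ] <- c(rep(-5, 10), rep(1, 10))
  expect_error(normalize_dff(movie_stack(bad)), "row 2, col 2")
})

test_that("running a preprocessing step twice raises a provenance error", {
  m <- movie_stack(array(runif(6 * 6 * 30, 1, 2), c(6, 6, 30)))
  sm <- smooth_frames(m)
  expect_step_error(smooth_frames(sm))
  dff <- normalize_dff(m)
  expect_step_error(normalize_dff(dff))
})

test_that("the chain recovers ground-truth dF/F0 from an artifact-laden movie", {
  cfg <- small_cfg(duration_s = 120, event_rate = 8, seed = 13, noise_sd = 1)
  clean <- generate_spontaneous_movie(cfg)
  set.seed(3)
  sh <- cbind(rnorm(1200, 0, 0.3), rnorm(1200, 0, 0.3))
  corrupted <- inject_artifacts(clean$movie, bleach = list(tau_s = 60),
                                shifts = sh)
  pp <- suppressWarnings(preprocess_movie(corrupted, clean$masks))
  ref <- suppressWarnings(preprocess_movie(clean$movie, clean$masks))
  a <- pp$movie$data; b <- ref$movie$data
  ok <- !is.na(a) & !is.na(b)
  expect_gt(cor(a[ok], b[ok]), 0.95)
})
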