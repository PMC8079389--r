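test_that("line scan of a row-uniform movie equals any single transect", {
  arr <- array(0, c(10, 8, 4))
  prof <- seq(0.1, 0.8, length.out = 8)
  for (t in 1:4) arr[, , t] <- matrix(prof * t, 10, 8, byrow = TRUE)
  ls <- compute_line_scan(movie_stack(arr), c(1, 1, 10, 8), angle = 0)
  expect_equal(dim(ls$values), c(8L, 4L))
  for (t in 1:4) expect_equal(ls$values[, t], prof * t, tolerance = 1e-12)
})

test_that("a synthetic band lands in the line-scan bin of its coordinate", {
  cfg <- small_cfg(duration_s = 60, event_rate = 2, coupling = 0,
                   noise_sd = 0, seed = 8, p_split = 0.999)
  g <- generate_spontaneous_movie(cfg)
  tr <- subset(g$truth, hemisphere == "L")
  expect_gt(nrow(tr), 0)
  dff <- normalize_dff(mask_movie(g$movie, g$masks))
  lb <- which(g$masks$left, arr.ind = TRUE)
  rect <- c(min(lb[, 1]), min(lb[, 2]), max(lb[, 1]), max(lb[, 2]))
  ls <- compute_line_scan(dff, rect, angle = 0)
  mid <- find_midline(g$masks)
  tono <- icbands:::hemi_tonotopy(g$masks$left, mid)
  for (i in seq_len(nrow(tr))) {
    expected_col <- icbands:::tonotopic_col(tr$p[i], tono)
    expected_bin <- expected_col - rect[2] + 1
    peak_bin <- which.max(ls$values[, min(tr$frame[i] + 1, ncol(ls$values))])
    expect_lt(abs(peak_bin - expected_bin), 2.5)
  }
})

test_that("tilted line scans reduce to straight ones at angle zero", {
  set.seed(2)
  arr <- array(runif(20 * 20 * 3), c(20, 20, 3))
  s0 <- compute_line_scan(movie_stack(arr), c(3, 3, 18, 18), angle = 0)
  s1 <- compute_line_scan(movie_stack(arr), c(3, 3, 18, 18), angle = 1e-9)
  expect_equal(dim(s1$values)[2], dim(s0$values)[2])
  expect_equal(s1$values[2:14, ], s0$values[2:14, ], tolerance = 1e-3)
})

make_map <- function(values, frame_rate = 10) {
  structure(list(values = values, angle = 0, rect = c(1, 1, 2, 2),
                 frame_rate = frame_rate), class = "LineScanMap")
}

gauss_bump <- function(nb, nt, b0, t0, amp, sb = 3, st = 4) {
  amp * outer(exp(-(seq_len(nb) - b0)^2 / (2 * sb^2)),
              exp(-(seq_len(nt) - t0)^2 / (2 * st^2)))
}

test_that("peak detection finds exactly the planted bumps above threshold", {
  expect_equal(nrow(detect_band_peaks(make_map(matrix(0, 30, 60)))), 0L)

  one <- make_map(gauss_bump(31, 61, 16, 31, 0.10))
  cat1 <- detect_band_peaks(one)
  expect_equal(nrow(cat1), 1L)
  expect_equal(cat1$bin, 16)
  expect_equal(cat1$frame, 31)

  weak <- make_map(gauss_bump(31, 61, 16, 31, 0.04))
  expect_equal(nrow(detect_band_peaks(weak)), 0L)

  expect_error(detect_band_peaks(one, amp_threshold = 0), "positive")
})

test_that("peaks on a multi-bump map match the 2-D neighborhood-max oracle", {
  set.seed(21)
  nb <- 60; nt <- 400
  m <- matrix(0, nb, nt)
  centers <- cbind(b = sample(8:(nb - 8), 20),
                   t = sample(seq(10, nt - 10, by = 19), 20))
  for (i in 1:20) m <- m + gauss_bump(nb, nt, centers[i, 1], centers[i, 2],
                                      runif(1, 0.08, 0.2))
  cat <- detect_band_peaks(make_map(m))
  # oracle: strict local maxima of the 5x5-smoothed map over the full 3x3
  # neighborhood, above threshold
  sm <- icbands:::box_mean(m, 5L)
  oracle <- NULL
  for (b in 2:(nb - 1)) for (t in 2:(nt - 1)) {
    nbh <- sm[(b - 1):(b + 1), (t - 1):(t + 1)]
    if (sm[b, t] >= 0.05 && sm[b, t] == max(nbh) &&
        sum(nbh == max(nbh)) == 1)
      oracle <- rbind(oracle, c(b, t))
  }
  expect_equal(nrow(cat), nrow(oracle))
  expect_setequal(paste(cat$bin, cat$frame), paste(oracle[, 1], oracle[, 2]))
})

test_that("detection is translation-equivariant in time", {
  m <- gauss_bump(31, 101, 16, 41, 0.12)
  c1 <- detect_band_peaks(make_map(m))
  shifted <- cbind(matrix(0, 31, 10), m[, 1:91])
  c2 <- detect_band_peaks(make_map(shifted))
  expect_equal(c2$frame, c1$frame + 10)
  expect_equal(c2$bin, c1$bin)
})

test_that("raising the detection threshold never increases the count", {
  set.seed(31)
  m <- matrix(0, 40, 200)
  for (i in 1:10) m <- m + gauss_bump(40, 200, sample(6:34, 1),
                                      sample(10:190, 1), runif(1, 0.03, 0.2))
  counts <- vapply(c(0.03, 0.05, 0.08, 0.12),
                   function(th) nrow(detect_band_peaks(make_map(m), th)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

fake_motion <- function(nfr, corrupted_frames) {
  df <- data.frame(frame = seq_len(nfr), dx = 0, dy = 0, amplitude = 0,
                   corrupted = seq_len(nfr) %in% corrupted_frames,
                   low_confidence = FALSE)
  df$amplitude[df$corrupted] <- 1
  class(df) <- c("MotionTrace", class(df))
  df
}

test_that("motion censoring follows the interval-overlap rule", {
  m <- gauss_bump(31, 101, 16, 50, 0.12)
  cat <- detect_band_peaks(make_map(m))
  expect_identical(censor_motion_events(cat, fake_motion(101, integer(0))),
                   cat)
  # event spans its temporal FWHM around frame 50; corrupt one inside frame
  inside <- round((cat$t_lo[1] + cat$t_hi[1]) / 2)
  expect_true(censor_motion_events(cat, fake_motion(101, inside))$censored)
  expect_false(censor_motion_events(cat, fake_motion(101, 5))$censored)
})

test_that("random censoring equals a brute-force interval-overlap oracle", {
  set.seed(41)
  m <- matrix(0, 50, 600)
  for (i in 1:15) m <- m + gauss_bump(50, 600, sample(8:42, 1),
                                      sample(15:585, 1), runif(1, 0.08, 0.2))
  cat <- detect_band_peaks(make_map(m))
  bad <- sample(600, 40)
  cen <- censor_motion_events(cat, fake_motion(600, bad))
  oracle <- vapply(seq_len(nrow(cat)), function(i)
    any(bad >= floor(cat$t_lo[i]) & bad <= ceiling(cat$t_hi[i])), logical(1))
  expect_equal(cen$censored, oracle)
})

test_that("event summaries implement the five statistics", {
  m <- gauss_bump(31, 600, 16, 300, 0.12)   # one event in a 1-min record
  s <- summarize_events(detect_band_peaks(make_map(m)))
  expect_equal(s$frequency_per_min, 1)

  # IPI oracle: frames {100, 100, 200, 350} at 10 Hz -> gaps 10 s, 15 s
  cat <- detect_band_peaks(make_map(m))[c(1, 1, 1, 1), ]
  cat$frame <- c(100L, 100L, 200L, 350L)
  attr(cat, "record_min") <- 1
  attr(cat, "frame_rate") <- 10
  attr(cat, "ic_width_bins") <- 31
  class(cat) <- c("EventCatalog", class(cat))
  s2 <- summarize_events(cat)
  expect_equal(s2$mean_ipi_s, 12.5)

  empty <- detect_band_peaks(make_map(matrix(0, 20, 60)))
  s3 <- summarize_events(empty)
  expect_equal(s3$frequency_per_min, 0)
  expect_true(is.na(s3$mean_duration_s))
})

test_that("the band-axis estimator returns near-zero angle for row bands", {
  arr <- array(0, c(30, 30, 5))
  arr[5:25, 14:16, ] <- 0.2              # vertical band along rows
  expect_lt(abs(estimate_band_axis(movie_stack(arr))), 5)
})
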