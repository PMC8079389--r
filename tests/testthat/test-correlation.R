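test_that("partial correlation agrees with the residual-regression oracle", {
  set.seed(1)
  x <- rnorm(1000); z <- rnorm(1000)
  expect_equal(partial_correlation(x, x + 1e-9 * rnorm(1000), z), 1,
               tolerance = 1e-6)
  for (i in 1:200) {
    n <- sample(20:200, 1)
    z <- rnorm(n)
    x <- rnorm(n) + runif(1, -2, 2) * z
    y <- rnorm(n) + runif(1, -2, 2) * z + runif(1, -1, 1) * x
    expect_equal(partial_correlation(x, y, z), partial_cor_oracle(x, y, z),
                 tolerance = 1e-10)
  }
})

test_that("a dependence fully mediated by the control vanishes", {
  set.seed(2)
  z <- rnorm(5000)
  x <- z + rnorm(5000)
  y <- z + rnorm(5000)
  expect_lt(abs(partial_correlation(x, y, z)), 0.05)
})

test_that("degenerate control traces are handled explicitly", {
  set.seed(3)
  x <- rnorm(100); y <- rnorm(100)
  expect_error(partial_correlation(x, y, x), "collinear")
  expect_message(r <- partial_correlation(x, y, rep(1, 100)), "Pearson")
  expect_equal(r, cor(x, y))
  expect_error(partial_correlation(rep(1, 100), y, x), "non-constant")
})

test_that("global bilateral correlation separates coupled from uncoupled", {
  g1 <- generate_spontaneous_movie(small_cfg(coupling = 1, noise_sd = 0,
                                             mirror_time_jitter = 0,
                                             mirror_pos_jitter = 0,
                                             duration_s = 120, seed = 7))
  r1 <- suppressMessages(
    global_bilateral_correlation(normalize_dff(g1$movie), g1$masks))
  expect_gt(r1, 0.9)

  g0 <- generate_spontaneous_movie(small_cfg(coupling = 0, duration_s = 600,
                                             event_rate = 6, seed = 3))
  r0 <- global_bilateral_correlation(normalize_dff(g0$movie), g0$masks)
  expect_lt(abs(r0), 0.1)
})

test_that("a duplicated hemisphere correlates at exactly 1", {
  set.seed(9)
  arr <- array(rnorm(12 * 12 * 300), c(12, 12, 300))
  arr[, 7:12, ] <- arr[, 6:1, ]          # right = mirror copy of left
  left <- matrix(FALSE, 12, 12); left[3:10, 2:5] <- TRUE
  right <- matrix(FALSE, 12, 12); right[3:10, 8:11] <- TRUE
  masks <- roi_mask_set(left, right)
  r <- global_bilateral_correlation(movie_stack(arr), masks)
  expect_equal(r, 1, tolerance = 1e-12)
})

test_that("seed maps equal per-pixel partial correlations", {
  set.seed(4)
  arr <- array(rnorm(16 * 16 * 500, mean = 1), c(16, 16, 500))
  left <- matrix(FALSE, 16, 16); left[3:14, 2:7] <- TRUE
  right <- matrix(FALSE, 16, 16); right[3:14, 10:15] <- TRUE
  masks <- roi_mask_set(left, right)
  seed <- c(8, 4)
  cmap <- seed_correlation_map(movie_stack(arr), seed, masks)
  expect_equal(cmap$r[seed[1], seed[2]], 1)
  expect_true(all(is.na(cmap$r[masks$outside])))
  z <- colMeans(matrix(arr, 256, 500)[which(masks$outside), ])
  sx <- arr[seed[1], seed[2], ]
  idx <- which(left | right, arr.ind = TRUE)
  for (i in sample(nrow(idx), 25)) {
    px <- idx[i, ]
    if (px[1] == seed[1] && px[2] == seed[2]) next
    expect_equal(cmap$r[px[1], px[2]],
                 partial_cor_oracle(sx, arr[px[1], px[2], ], z),
                 tolerance = 1e-10)
  }
})

test_that("on coupled data the contralateral maximum sits at the mirror band", {
  cfg <- small_cfg(coupling = 1, mirror_time_jitter = 0,
                   mirror_pos_jitter = 0, duration_s = 300, event_rate = 8,
                   noise_sd = 1, seed = 17)
  g <- generate_spontaneous_movie(cfg)
  dff <- normalize_dff(g$movie)
  mid <- find_midline(g$masks)
  lpx <- which(g$masks$left, arr.ind = TRUE)
  seed <- lpx[which.min(abs(lpx[, 1] - mean(lpx[, 1])) +
                          abs(lpx[, 2] - mean(lpx[, 2]))), ]
  cmap <- seed_correlation_map(dff, seed, g$masks)
  mx <- max_symmetric_region_correlation(cmap, mirror_mask(g$masks$left, mid))
  # the mirrored seed column hosts the homologous band
  expect_lt(abs(mx$location["col"] - round(2 * mid - seed[2])), 3)
  expect_gt(mx$r_max, 0.5)
})

test_that("seed lattices are evenly spaced, deterministic, centred", {
  g <- build_seed_grid(c(100, 100), 1000)
  expect_gte(nrow(g), 1000)
  rs <- sort(unique(g$row)); cs <- sort(unique(g$col))
  expect_lt(diff(range(diff(rs))), 1 + 1e-9)
  expect_lt(diff(range(diff(cs))), 1 + 1e-9)
  expect_identical(g, build_seed_grid(c(100, 100), 1000))

  g1 <- build_seed_grid(c(21, 31), 1)
  expect_equal(c(g1$row, g1$col), c(11, 16))
})

test_that("neighborhood-mean maximum search honours region and ties", {
  rmat <- matrix(0.3, 20, 20)
  region <- matrix(FALSE, 20, 20); region[4:17, 4:17] <- TRUE
  cmap <- structure(list(r = rmat, seed = c(1, 1), control = "x",
                         frames_used = 1:10), class = "CorrelationMap")
  mx <- max_symmetric_region_correlation(cmap, region)
  expect_equal(mx$r_max, 0.3)

  rmat2 <- matrix(0.1, 20, 20)
  rmat2[8:12, 9:13] <- 0.9               # planted 5x5 patch
  cmap2 <- structure(list(r = rmat2, seed = c(1, 1), control = "x",
                          frames_used = 1:10), class = "CorrelationMap")
  mx2 <- max_symmetric_region_correlation(cmap2, region)
  expect_equal(unname(mx2$location), c(10, 11))
  expect_equal(mx2$r_max, 0.9)

  # high values outside the region are ignored
  rmat3 <- rmat2; rmat3[1, 1] <- 1
  cmap3 <- structure(list(r = rmat3, seed = c(1, 1), control = "x",
                          frames_used = 1:10), class = "CorrelationMap")
  expect_equal(max_symmetric_region_correlation(cmap3, region)$r_max, 0.9)
})

test_that("region morphology matches second-moment oracles", {
  mk_map <- function(bw, seed) structure(
    list(r = ifelse(bw, 0.99, 0), seed = seed, control = "x",
         frames_used = 1:10), class = "CorrelationMap")
  rows <- matrix(1:60, 60, 60); cols <- matrix(1:60, 60, 60, byrow = TRUE)
  hemi <- matrix(TRUE, 60, 60)

  disc <- (rows - 30)^2 + (cols - 30)^2 <= 15^2
  rp <- correlation_region_properties(mk_map(disc, c(30, 30)), hemi)
  expect_gte(rp$eccentricity, 1)
  expect_lte(rp$eccentricity, 1.1)

  ell <- ((rows - 30) / 20)^2 + ((cols - 30) / 5)^2 <= 1
  rp2 <- correlation_region_properties(mk_map(ell, c(30, 30)), hemi)
  expect_equal(rp2$eccentricity, 4, tolerance = 0.1)

  hemi2 <- matrix(FALSE, 60, 60); hemi2[1:1000] <- TRUE
  small_disc <- matrix(FALSE, 60, 60)
  small_disc[which(disc)[1:100]] <- TRUE
  rp3 <- correlation_region_properties(
    mk_map(small_disc, which(small_disc, arr.ind = TRUE)[1, ]), hemi2)
  expect_equal(rp3$proportion, 0.1)

  expect_error(correlation_region_properties(mk_map(disc, c(1, 1)), hemi),
               "component")
})

test_that("representative seeds track the single/dual band transition", {
  cfg <- small_cfg(coupling = 1, duration_s = 300, event_rate = 10,
                   noise_sd = 1, seed = 23)
  g <- generate_spontaneous_movie(cfg)
  dff <- normalize_dff(g$movie)
  sel <- select_representative_seeds(dff, g$masks,
                                     grid = build_seed_grid(dim(dff)[1:2],
                                                            1000, g$masks))
  expect_false(is.null(sel$low))
  expect_true(g$masks$left[sel$low[1], sel$low[2]])
  # low seed is medial (single-band zone), mid/high lateral of it
  mid <- find_midline(g$masks)
  if (!is.null(sel$mid)) {
    expect_gt(abs(sel$mid["col"] - mid), abs(sel$low["col"] - mid))
  }
  sel2 <- select_representative_seeds(dff, g$masks,
                                      grid = build_seed_grid(dim(dff)[1:2],
                                                             1000, g$masks))
  expect_identical(sel, sel2)
})

test_that("movies without dual-band structure report missing mid/high seeds", {
  cfg <- small_cfg(coupling = 1, duration_s = 200, event_rate = 8,
                   noise_sd = 1, seed = 27, p_split = 0.999)
  g <- generate_spontaneous_movie(cfg)
  dff <- normalize_dff(g$movie)
  sel <- select_representative_seeds(dff, g$masks)
  expect_null(sel$high)
})

test_that("all reported correlations stay within [-1, 1] and the ROI", {
  cfg <- small_cfg(duration_s = 120, seed = 29, event_rate = 8)
  g <- generate_spontaneous_movie(cfg)
  dff <- normalize_dff(g$movie)
  lpx <- which(g$masks$left, arr.ind = TRUE)
  cmap <- seed_correlation_map(dff, lpx[10, ], g$masks)
  vals <- cmap$r[!is.na(cmap$r)]
  expect_true(all(vals >= -1 - 1e-12 & vals <= 1 + 1e-12))
  expect_true(all(is.na(cmap$r[g$masks$outside])))
})
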