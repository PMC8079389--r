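#' Photobleaching correction
#'
#' Fits a single-term exponential `f(t) = A * exp(-t / tau)` to the
#' frame-wise mean fluorescence by log-linear least squares and divides each
#' frame by `f(t) / f(0)`, so the correction is multiplicative and preserves
#' the frame-0 scale. A non-decaying trace makes the fit degenerate; the
#' movie is then returned unchanged with a flagged `BleachFit`.
#'
#' @param movie a [movie_stack()] with at least 10 frames.
#' @return List with `movie` (corrected) and `fit` (a `BleachFit`: `A`,
#'   `tau_frames`, `rate_per_frame`, `residual_rms`, `degenerate`).
#' @export
correct_photobleach <- function(movie) {
  stopifnot(inherits(movie, "MovieStack"))
  nfr <- n_frames(movie)
  if (nfr < 10L) stop("photobleach correction needs at least 10 frames",
                      call. = FALSE)
  movie <- mark_step(movie, "photobleach")
  mu <- apply(movie$data, 3L, mean, na.rm = TRUE)
  t0 <- seq_len(nfr) - 1
  degen <- any(mu <= 0)
  fit <- NULL
  if (!degen) {
    co <- stats::lm.fit(cbind(1, t0), log(mu))$coefficients
    if (co[2L] >= 0) degen <- TRUE else fit <- co
  }
  if (degen) {
    warning("bleach fit degenerate (non-decaying frame-mean trace); ",
            "movie returned unchanged")
    bf <- structure(list(A = NA_real_, tau_frames = NA_real_,
                         rate_per_frame = NA_real_, residual_rms = NA_real_,
                         degenerate = TRUE), class = "BleachFit")
    return(list(movie = movie, fit = bf))
  }
  A <- exp(fit[1L]); rate <- -fit[2L]
  f <- A * exp(-rate * t0)
  corr <- f / f[1L]
  movie$data <- movie$data / rep(corr, each = prod(dim(movie$data)[1:2]))
  bf <- structure(list(A = unname(A), tau_frames = unname(1 / rate),
                       rate_per_frame = unname(rate),
                       residual_rms = sqrt(mean((mu - f)^2)),
                       degenerate = FALSE), class = "BleachFit")
  list(movie = movie, fit = bf)
}

# Subpixel shift estimate by Fourier phase correlation: integer peak of the
# normalized cross-power spectrum within a bounded search radius, refined on
# a 10x-upsampled local DFT grid. The radius excludes the self-similarity
# alias of the bilateral field (two near-identical hemisphere patterns one
# hemisphere spacing apart); genuine rigid brain motion is far smaller.
# Returns (dy, dx) such that frame ~= ref translated by (dy, dx).
phase_shift_estimate <- function(ref, frame, upsample = 10L, max_shift = 5) {
  nr <- nrow(ref); nc <- ncol(ref)
  Fr <- fft(ref - mean(ref)); Ff <- fft(frame - mean(frame))
  # un-normalized cross power: whitening overweights frequencies where a
  # blurred mean reference carries no signal and biases the peak
  R <- Ff * Conj(Fr)
  cc <- Re(fft(R, inverse = TRUE)) / (nr * nc)
  lag_r <- ifelse(0:(nr - 1L) > nr / 2, 0:(nr - 1L) - nr, 0:(nr - 1L))
  lag_c <- ifelse(0:(nc - 1L) > nc / 2, 0:(nc - 1L) - nc, 0:(nc - 1L))
  cc[abs(lag_r) > max_shift, ] <- -Inf
  cc[, abs(lag_c) > max_shift] <- -Inf
  pk <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
  d0 <- c(lag_r[pk[1L]], lag_c[pk[2L]])
  # successive local upsampled-DFT refinements around the integer estimate
  kr <- ((seq_len(nr) - 1L + floor(nr / 2)) %% nr) - floor(nr / 2)
  kc <- ((seq_len(nc) - 1L + floor(nc / 2)) %% nc) - floor(nc / 2)
  d <- d0
  halfwin <- 1
  for (pass in 1:2) {
    ur <- d[1L] + seq(-halfwin, halfwin, by = halfwin / upsample)
    uc <- d[2L] + seq(-halfwin, halfwin, by = halfwin / upsample)
    Er <- exp(2i * pi * outer(ur, kr) / nr)
    Ec <- exp(2i * pi * outer(kc, uc) / nc)
    grid <- Re(Er %*% R %*% Ec)
    best <- which(grid == max(grid), arr.ind = TRUE)[1L, ]
    d <- c(ur[best[1L]], uc[best[2L]])
    halfwin <- halfwin / upsample
  }
  c(dy = d[1L], dx = d[2L])
}

#' Subpixel rigid registration
#'
#' Estimates a per-frame rigid translation against a reference frame by
#' Fourier phase correlation with 10x upsampling, applies the inverse shift
#' (bilinear, edge-replicated), and flags frames whose shift amplitude
#' exceeds `motion_threshold` as motion-corrupted; downstream statistics
#' exclude those frames.
#'
#' @param movie a [movie_stack()].
#' @param reference `"mean"` (session mean frame) or a frame index.
#' @param motion_threshold corruption threshold on the shift amplitude, px.
#' @param max_shift search radius for the translation estimate, px.
#' @return List with `movie` (registered) and `motion` (a `MotionTrace` data
#'   frame: `frame`, `dx`, `dy`, `amplitude`, `corrupted`, `low_confidence`).
#' @export
register_frames <- function(movie, reference = "mean", motion_threshold = 0.5,
                            max_shift = 5) {
  stopifnot(inherits(movie, "MovieStack"))
  movie <- mark_step(movie, "register")
  d <- dim(movie$data)
  ref <- if (identical(reference, "mean")) {
    apply(movie$data, c(1L, 2L), mean)
  } else {
    stopifnot(reference >= 1L, reference <= d[3L])
    movie$data[, , reference]
  }
  dy <- dx <- numeric(d[3L]); lowconf <- logical(d[3L])
  for (t in seq_len(d[3L])) {
    fr <- movie$data[, , t]
    if (sd(fr) == 0) { lowconf[t] <- TRUE; next }  # no structure
    s <- phase_shift_estimate(ref, fr, max_shift = max_shift)
    dy[t] <- s[1L]; dx[t] <- s[2L]
    if (dy[t] != 0 || dx[t] != 0)
      movie$data[, , t] <- shift_frame(fr, -dy[t], -dx[t])
  }
  amp <- sqrt(dx^2 + dy^2)
  motion <- data.frame(frame = seq_len(d[3L]), dx = dx, dy = dy,
                       amplitude = amp,
                       corrupted = amp > motion_threshold,
                       low_confidence = lowconf)
  attr(motion, "threshold_px") <- motion_threshold
  class(motion) <- c("MotionTrace", class(motion))
  list(movie = movie, motion = motion)
}

#' Gaussian smoothing
#'
#' Per-frame 2-D convolution with a normalized Gaussian kernel (`sigma` px,
#' truncated at 4 sigma), replicate boundary handling.
#'
#' @param movie a [movie_stack()].
#' @param sigma Gaussian SD in px.
#' @return The smoothed `MovieStack`.
#' @export
smooth_frames <- function(movie, sigma = 1) {
  stopifnot(inherits(movie, "MovieStack"), sigma > 0)
  movie <- mark_step(movie, "smooth")
  k <- gaussian_kernel(sigma)
  h <- (nrow(k) - 1L) %/% 2L
  d <- dim(movie$data)
  # replicate-pad so the kernel never exceeds the frame and the boundary
  # rule is exactly edge replication, then crop back
  ri <- c(rep(1L, h), seq_len(d[1L]), rep(d[1L], h))
  ci <- c(rep(1L, h), seq_len(d[2L]), rep(d[2L], h))
  padded <- movie$data[ri, ci, , drop = FALSE]
  sm <- EBImage::filter2(padded, k, boundary = "circular")
  movie$data <- array(sm, dim = dim(padded))[h + seq_len(d[1L]),
                                             h + seq_len(d[2L]), ,
                                             drop = FALSE]
  movie
}

#' ROI masking and 2x2 average pooling
#'
#' Sets out-of-ROI pixels to `NA` (the missing marker excluded from all
#' downstream statistics) and halves both spatial dimensions by averaging
#' disjoint 2x2 blocks. Blocks straddling the ROI boundary average their
#' in-ROI members only; all-outside blocks stay `NA`. Odd trailing rows or
#' columns are dropped with a warning.
#'
#' @param movie a [movie_stack()].
#' @param masks a [roi_mask_set()] matching the movie dimensions.
#' @return List with `movie` (masked, downsampled) and `masks` (the mask set
#'   downsampled to the new grid).
#' @export
mask_and_downsample <- function(movie, masks) {
  stopifnot(inherits(movie, "MovieStack"), inherits(masks, "RoiMaskSet"))
  d <- dim(movie$data)
  stopifnot(all(dim(masks$left) == d[1:2]))
  movie <- mark_step(movie, "mask_downsample")
  roi <- in_roi_mask(masks)
  if (d[1L] %% 2L || d[2L] %% 2L) {
    warning("odd movie dimensions: trailing row/col dropped before pooling")
  }
  nr <- (d[1L] %/% 2L) * 2L; nc <- (d[2L] %/% 2L) * 2L
  arr <- movie$data[seq_len(nr), seq_len(nc), , drop = FALSE]
  arr[!roi[seq_len(nr), seq_len(nc)]] <- NA_real_
  ds <- pool2x2(arr)
  movie$data <- ds
  list(movie = movie, masks = downsample_masks(masks))
}

# NA-aware disjoint 2x2 block mean of a (rows, cols, frames) array.
pool2x2 <- function(arr) {
  d <- dim(arr)
  nr2 <- d[1L] %/% 2L; nc2 <- d[2L] %/% 2L
  ok <- !is.na(arr)
  v <- arr; v[!ok] <- 0
  blk <- function(a) {
    a <- a[seq_len(2L * nr2), seq_len(2L * nc2), , drop = FALSE]
    a <- a[seq(1, 2 * nr2, 2), , , drop = FALSE] +
      a[seq(2, 2 * nr2, 2), , , drop = FALSE]
    a[, seq(1, 2 * nc2, 2), , drop = FALSE] +
      a[, seq(2, 2 * nc2, 2), , drop = FALSE]
  }
  sums <- blk(v)
  cnts <- blk(ok + 0)
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  out
}

#' Downsample a mask set to the 2x2-pooled grid
#'
#' A pooled pixel belongs to a hemisphere when any member of its 2x2 block
#' does; the outside region is the complement.
#'
#' @param masks a [roi_mask_set()].
#' @return The pooled `RoiMaskSet`.
#' @export
downsample_masks <- function(masks) {
  ds1 <- function(m) {
    a <- array(m + 0, dim = c(dim(m), 1L))
    p <- pool2x2(a)
    matrix(p[, , 1L] > 0, dim(p)[1L], dim(p)[2L])
  }
  roi_mask_set(left = ds1(masks$left), right = ds1(masks$right))
}

#' SVD denoising
#'
#' Forms the in-ROI pixels-by-frames matrix, keeps the leading singular
#' components (by rank `k` or by cumulative squared-singular-value energy
#' `var_fraction`), and reconstructs. By Eckart-Young the squared
#' reconstruction error equals the discarded tail energy.
#'
#' @param movie a [movie_stack()] (masked pixels stay `NA`).
#' @param k number of components to keep; overrides `var_fraction`.
#' @param var_fraction fraction of total energy to retain (default 0.9).
#' @return The denoised `MovieStack` with attribute `svd_rank`.
#' @export
svd_denoise <- function(movie, k = NULL, var_fraction = 0.9) {
  stopifnot(inherits(movie, "MovieStack"))
  movie <- mark_step(movie, "svd_denoise")
  d <- dim(movie$data)
  m <- matrix(movie$data, d[1L] * d[2L], d[3L])
  inpx <- which(!is.na(m[, 1L]))
  X <- m[inpx, , drop = FALSE]
  s <- svd(X)
  r <- sum(s$d > max(dim(X)) * .Machine$double.eps * s$d[1L])
  if (is.null(k)) {
    # the leading component is the (static) baseline pattern and dominates
    # the raw energy; rank selection applies the energy fraction to the
    # fluctuation components and always keeps the first
    if (r <= 1L) k <- 1L else {
      tail2 <- s$d[2:r]^2
      en <- cumsum(tail2) / sum(tail2)
      k <- 1L + which(en >= var_fraction)[1L]
    }
  }
  if (k >= r) {
    if (k > r) warning("requested rank exceeds matrix rank; keeping all ",
                       r, " components")
    k <- r
  }
  kk <- seq_len(k)
  X2 <- s$u[, kk, drop = FALSE] %*%
    (s$d[kk] * t(s$v[, kk, drop = FALSE]))
  m[inpx, ] <- X2
  movie$data <- array(m, dim = d)
  attr(movie, "svd_rank") <- k
  movie
}

#' dF/F0 normalization
#'
#' Per-pixel baseline `F0` is a low percentile of that pixel's own trace
#' (default the 5th, linear interpolation between order statistics);
#' the movie becomes `(F - F0) / F0`.
#'
#' @param movie a [movie_stack()].
#' @param f0_percentile baseline percentile (0-100).
#' @return The normalized `MovieStack`.
#' @export
normalize_dff <- function(movie, f0_percentile = 5) {
  stopifnot(inherits(movie, "MovieStack"),
            f0_percentile > 0, f0_percentile < 100)
  movie <- mark_step(movie, "dff")
  d <- dim(movie$data)
  f0 <- pixel_quantile(movie$data, f0_percentile / 100)
  bad <- which(!is.na(f0) & f0 <= 0)
  if (length(bad)) {
    rc <- arrayInd(bad[1L], d[1:2])
    stop(sprintf("F0 <= 0 at in-ROI pixel (row %d, col %d)", rc[1L], rc[2L]),
         call. = FALSE)
  }
  movie$data <- (movie$data - rep(f0, d[3L])) / rep(f0, d[3L])
  movie
}

#' Run the full preprocessing chain
#'
#' Applies, in order: photobleach correction, subpixel registration, Gaussian
#' smoothing, ROI masking + 2x2 pooling, SVD denoising and dF/F0
#' normalization. The evoked workflow sets `normalize = FALSE` and normalizes
#' after trial averaging instead.
#'
#' @param movie a raw [movie_stack()].
#' @param masks a [roi_mask_set()] on the raw pixel grid.
#' @param smooth_sigma Gaussian SD, px.
#' @param svd_var_fraction SVD energy fraction retained.
#' @param svd_k optional explicit SVD rank.
#' @param f0_percentile dF/F0 baseline percentile.
#' @param motion_threshold motion-corruption threshold, px.
#' @param normalize run the final dF/F0 step.
#' @return List with `movie`, `masks` (downsampled), `bleach`, `motion`.
#' @export
preprocess_movie <- function(movie, masks, smooth_sigma = 1,
                             svd_var_fraction = 0.9, svd_k = NULL,
                             f0_percentile = 5, motion_threshold = 0.5,
                             normalize = TRUE) {
  pb <- correct_photobleach(movie)
  rg <- register_frames(pb$movie, motion_threshold = motion_threshold)
  # the outside-ROI control trace is captured before smoothing (which would
  # leak ROI activity into boundary background pixels and contaminate the
  # control regressor) and before masking drops the background entirely
  outside_trace <- mask_mean_trace(rg$movie, masks$outside)
  sm <- smooth_frames(rg$movie, sigma = smooth_sigma)
  md <- mask_and_downsample(sm, masks)
  dn <- svd_denoise(md$movie, k = svd_k, var_fraction = svd_var_fraction)
  out <- if (normalize) normalize_dff(dn, f0_percentile) else dn
  attr(out, "outside_trace") <- outside_trace
  list(movie = out, masks = md$masks, bleach = pb$fit, motion = rg$motion)
}
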