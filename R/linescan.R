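#' Reduce a movie to a line-scan map across the tonotopic axis
#'
#' Averages the movie over the direction parallel to the major axis of the
#' spontaneous bands within a rectangular region, reducing each 2-D frame to
#' a 1-D transect across the tonotopic axis, i.e. a 3-D movie to a 2-D
#' (position bin x frame) map. With `angle = 0` the major axis runs along
#' image rows and each bin is simply a column mean of the rectangle; for
#' other angles the rectangle is sampled along tilted lines with bilinear
#' interpolation.
#'
#' @param movie a [movie_stack()] (typically dF/F0).
#' @param rect `c(r0, c0, r1, c1)` rectangle in pixel coordinates.
#' @param angle major-axis angle in degrees away from the image row axis.
#' @param min_pixels minimum in-ROI pixels per line.
#' @return A `LineScanMap`: list with `values` (bins x frames), `angle`,
#'   `rect`, `frame_rate`.
#' @export
compute_line_scan <- function(movie, rect, angle = 0, min_pixels = 3L) {
  stopifnot(inherits(movie, "MovieStack"), length(rect) == 4L)
  d <- dim(movie$data)
  r0 <- rect[1L]; c0 <- rect[2L]; r1 <- rect[3L]; c1 <- rect[4L]
  stopifnot(r0 >= 1, c0 >= 1, r1 <= d[1L], c1 <= d[2L], r0 < r1, c0 < c1)
  if (angle == 0) {
    sub <- movie$data[r0:r1, c0:c1, , drop = FALSE]
    cnt <- colSums(!is.na(sub[, , 1L, drop = FALSE][, , 1L]))
    if (any(cnt > 0 & cnt < min_pixels))
      stop("line-scan rectangle has lines with fewer than ", min_pixels,
           " in-ROI pixels", call. = FALSE)
    vals <- colMeans(sub, na.rm = TRUE, dims = 1L)
    vals[cnt == 0, ] <- NA_real_
  } else {
    th <- angle * pi / 180
    major <- c(cos(th), sin(th))          # (d_row, d_col) unit vectors
    tono <- c(-sin(th), cos(th))
    corners <- rbind(c(r0, c0), c(r0, c1), c(r1, c0), c(r1, c1))
    ctr <- c((r0 + r1) / 2, (c0 + c1) / 2)
    proj_t <- (corners - matrix(ctr, 4, 2, byrow = TRUE)) %*% tono
    proj_m <- (corners - matrix(ctr, 4, 2, byrow = TRUE)) %*% major
    tpos <- seq(min(proj_t), max(proj_t))
    mpos <- seq(min(proj_m), max(proj_m))
    vals <- matrix(NA_real_, length(tpos), d[3L])
    for (i in seq_along(tpos)) {
      pts <- cbind(ctr[1L] + tpos[i] * tono[1L] + mpos * major[1L],
                   ctr[2L] + tpos[i] * tono[2L] + mpos * major[2L])
      eps <- 1e-6                        # tolerate fp jitter at the borders
      keep <- pts[, 1L] >= r0 - eps & pts[, 1L] <= r1 + eps &
        pts[, 2L] >= c0 - eps & pts[, 2L] <= c1 + eps
      pts <- pts[keep, , drop = FALSE]
      if (nrow(pts) == 0L) next
      samp <- bilinear_sample(movie$data, pts)
      npx <- colSums(!is.na(samp))
      if (all(npx == 0)) next
      if (any(npx > 0 & npx < min_pixels))
        stop("line-scan rectangle has lines with fewer than ", min_pixels,
             " in-ROI pixels", call. = FALSE)
      vals[i, ] <- colMeans(samp, na.rm = TRUE)
    }
  }
  structure(list(values = vals, angle = angle, rect = rect,
                 frame_rate = movie$frame_rate), class = "LineScanMap")
}

# Bilinear samples of every frame at fractional (row, col) points; returns a
# points x frames matrix.
bilinear_sample <- function(arr, pts) {
  d <- dim(arr)
  y0 <- pmin(pmax(floor(pts[, 1L]), 1L), d[1L]); y1 <- pmin(y0 + 1L, d[1L])
  x0 <- pmin(pmax(floor(pts[, 2L]), 1L), d[2L]); x1 <- pmin(x0 + 1L, d[2L])
  fy <- pmin(pmax(pts[, 1L] - y0, 0), 1); fx <- pmin(pmax(pts[, 2L] - x0, 0), 1)
  m <- matrix(arr, d[1L] * d[2L], d[3L])
  idx <- function(y, x) (x - 1L) * d[1L] + y
  m[idx(y0, x0), , drop = FALSE] * ((1 - fy) * (1 - fx)) +
    m[idx(y1, x0), , drop = FALSE] * (fy * (1 - fx)) +
    m[idx(y0, x1), , drop = FALSE] * ((1 - fy) * fx) +
    m[idx(y1, x1), , drop = FALSE] * (fy * fx)
}

#' Estimate the band major-axis angle from mean activity
#'
#' Orientation (second image moments) of the thresholded temporal-mean
#' activity image; a stand-in for the interactive axis choice, always
#' overridable.
#'
#' @param movie a dF/F0 [movie_stack()].
#' @param mask logical matrix restricting the estimate.
#' @param q quantile of the mean image used as threshold.
#' @return Angle in degrees away from the row axis.
#' @export
estimate_band_axis <- function(movie, mask = NULL, q = 0.9) {
  img <- apply(movie$data, c(1L, 2L), mean, na.rm = TRUE)
  if (!is.null(mask)) img[!mask] <- NA
  thr <- quantile(img, q, na.rm = TRUE)
  px <- which(!is.na(img) & img > thr, arr.ind = TRUE)
  if (nrow(px) < 3L) return(0)
  cv <- stats::cov(px)
  e <- eigen(cv, symmetric = TRUE)
  v <- e$vectors[, 1L]                   # major direction (d_row, d_col)
  ang <- atan2(v[2L], v[1L]) * 180 / pi
  if (ang > 90) ang <- ang - 180
  if (ang <= -90) ang <- ang + 180
  ang
}

#' Detect spatiotemporal band peaks in a line-scan map
#'
#' Smooths the map with a 5x5 mean filter, finds 1-D local maxima
#' independently along the spatial direction (within each frame) and along
#' the temporal direction (within each position bin), and keeps the
#' locations marked by both scans whose smoothed amplitude reaches
#' `amp_threshold` (5\% dF/F0 by default). Spatial and temporal half-widths
#' are full widths at half maximum measured on the smoothed map, referenced
#' to the map's event-free baseline (its median) so that the small positive
#' pedestal left by percentile-based dF/F0 normalization does not inflate
#' widths; events clipped by the record edge keep twice the measurable side
#' and are flagged.
#'
#' @param map a [compute_line_scan()] result.
#' @param amp_threshold detection threshold, dF/F0.
#' @param smooth_k side of the square mean filter (default 5).
#' @param ic_width_bins IC width used later for bandwidth normalization;
#'   defaults to the number of line-scan bins.
#' @return An `EventCatalog` data frame: `frame`, `bin`, `amplitude`,
#'   `t_fwhm_s`, `s_fwhm_bins`, `t_lo`, `t_hi`, `edge`, `censored`.
#' @export
detect_band_peaks <- function(map, amp_threshold = 0.05, smooth_k = 5L,
                              ic_width_bins = NULL) {
  stopifnot(inherits(map, "LineScanMap"))
  if (amp_threshold <= 0) stop("amp_threshold must be positive", call. = FALSE)
  v <- map$values
  v[is.na(v)] <- 0
  sm <- box_mean(v, smooth_k)
  nb <- nrow(sm); nt <- ncol(sm)
  spatial <- matrix(FALSE, nb, nt)
  for (t in seq_len(nt)) spatial[local_maxima_1d(sm[, t]), t] <- TRUE
  temporal <- matrix(FALSE, nb, nt)
  for (b in seq_len(nb)) temporal[b, local_maxima_1d(sm[b, ])] <- TRUE
  hits <- which(spatial & temporal & sm >= amp_threshold, arr.ind = TRUE)
  base <- median(sm)
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    b <- hits[i, 1L]; t <- hits[i, 2L]
    ft <- fwhm_1d(sm[b, ], t, baseline = base)
    fs <- fwhm_1d(sm[, t], b, baseline = base)
    data.frame(frame = t, bin = b, amplitude = sm[b, t],
               t_fwhm_s = ft$width / map$frame_rate,
               s_fwhm_bins = fs$width,
               t_lo = ft$lo, t_hi = ft$hi,
               edge = ft$edge || fs$edge, censored = FALSE)
  })
  cat <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(), bin = integer(), amplitude = numeric(),
               t_fwhm_s = numeric(), s_fwhm_bins = numeric(),
               t_lo = numeric(), t_hi = numeric(), edge = logical(),
               censored = logical())
  attr(cat, "record_min") <- nt / map$frame_rate / 60
  attr(cat, "frame_rate") <- map$frame_rate
  attr(cat, "ic_width_bins") <- ic_width_bins %||% nb
  class(cat) <- c("EventCatalog", class(cat))
  cat
}

#' Censor motion-corrupted events
#'
#' Flags events whose temporal FWHM interval overlaps any frame marked
#' motion-corrupted; flagged events are excluded from all summaries.
#'
#' @param catalog an `EventCatalog`.
#' @param motion a `MotionTrace` covering the record.
#' @return The catalog with `censored` updated.
#' @export
censor_motion_events <- function(catalog, motion) {
  stopifnot(inherits(catalog, "EventCatalog"), inherits(motion, "MotionTrace"))
  bad <- motion$frame[motion$corrupted]
  if (length(bad) && nrow(catalog)) {
    catalog$censored <- vapply(seq_len(nrow(catalog)), function(i) {
      any(bad >= floor(catalog$t_lo[i]) & bad <= ceiling(catalog$t_hi[i]))
    }, logical(1))
  }
  catalog
}

#' Summarize an event catalog
#'
#' The five spatiotemporal statistics: event frequency (retained events per
#' minute), mean duration (temporal FWHM, s), mean inter-peak interval
#' (same-frame peaks collapsed to one event so intervals are never zero),
#' normalized bandwidth (mean spatial FWHM over IC width), and mean peak
#' amplitude (dF/F0).
#'
#' @param catalog an `EventCatalog`.
#' @return An `EventSummary` data frame with one row.
#' @export
summarize_events <- function(catalog) {
  stopifnot(inherits(catalog, "EventCatalog"))
  mins <- attr(catalog, "record_min")
  if (is.null(mins) || mins <= 0) stop("record length must be positive",
                                       call. = FALSE)
  keep <- catalog[!catalog$censored, , drop = FALSE]
  if (nrow(keep) == 0L) {
    out <- data.frame(frequency_per_min = 0, mean_duration_s = NA_real_,
                      mean_ipi_s = NA_real_, norm_bandwidth = NA_real_,
                      mean_amplitude = NA_real_, n_events = 0L)
  } else {
    fr <- sort(unique(keep$frame))
    ipi <- if (length(fr) > 1L) mean(diff(fr)) / attr(catalog, "frame_rate")
    else NA_real_
    out <- data.frame(
      frequency_per_min = nrow(keep) / mins,
      mean_duration_s = mean(keep$t_fwhm_s, na.rm = TRUE),
      mean_ipi_s = ipi,
      norm_bandwidth = mean(keep$s_fwhm_bins, na.rm = TRUE) /
        attr(catalog, "ic_width_bins"),
      mean_amplitude = mean(keep$amplitude),
      n_events = nrow(keep))
  }
  class(out) <- c("EventSummary", class(out))
  out
}
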