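#' First-order partial correlation
#'
#' Correlation between `x` and `y` after removing the linear contribution of
#' the control trace `z`:
#' `r_xy.z = (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) (1 - r_yz^2))`,
#' identical to the Pearson correlation of the residuals of `x` and `y` each
#' regressed on `z`. Used throughout with the outside-ROI mean trace as `z`
#' to regress out non-specific whole-brain fluctuations.
#'
#' @param x,y numeric traces of equal length (>= 3), non-constant.
#' @param z control trace; if constant, plain Pearson is returned with a
#'   message.
#' @return The partial correlation coefficient.
#' @export
partial_correlation <- function(x, y, z) {
  n <- length(x)
  stopifnot(n >= 3L, length(y) == n, length(z) == n)
  if (sd(x) == 0 || sd(y) == 0)
    stop("x and y must be non-constant", call. = FALSE)
  if (sd(z) == 0) {
    message("constant control trace: falling back to plain Pearson")
    return(cor(x, y))
  }
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  if (abs(rxz) >= 1 - 1e-14 || abs(ryz) >= 1 - 1e-14)
    stop("control trace is collinear with x or y; partial correlation ",
         "undefined", call. = FALSE)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# Frames retained for correlation analysis: drop motion-corrupted ones.
frames_kept <- function(nfr, motion = NULL) {
  if (is.null(motion)) return(seq_len(nfr))
  keep <- setdiff(seq_len(nfr), motion$frame[motion$corrupted])
  if (length(keep) < 3L) stop("all frames motion-corrupted", call. = FALSE)
  keep
}

# Mean trace over the TRUE pixels of `mask`, NA pixels skipped.
mask_mean_trace <- function(movie, mask) {
  d <- dim(movie$data)
  m <- matrix(movie$data, d[1L] * d[2L], d[3L])
  sel <- m[which(mask), , drop = FALSE]
  colMeans(sel, na.rm = TRUE)
}

#' Global bilateral correlation
#'
#' Partial correlation between the two hemisphere-mean dF/F0 traces,
#' controlling for the mean trace over all pixels outside the IC and
#' excluding motion-corrupted frames.
#'
#' @param movie a dF/F0 [movie_stack()] on the downsampled grid.
#' @param masks a [roi_mask_set()] on the same grid; a non-empty outside
#'   region is required (it provides the control regressor).
#' @param motion optional `MotionTrace`; corrupted frames are dropped.
#' @return The global bilateral correlation coefficient.
#' @export
global_bilateral_correlation <- function(movie, masks, motion = NULL) {
  stopifnot(inherits(movie, "MovieStack"), inherits(masks, "RoiMaskSet"))
  if (!any(masks$left) || !any(masks$right))
    stop("both hemisphere masks must be non-empty", call. = FALSE)
  if (!any(masks$outside))
    stop("no outside-ROI region: the partial-correlation control regressor ",
         "requires pixels outside the IC", call. = FALSE)
  keep <- frames_kept(n_frames(movie), motion)
  l <- mask_mean_trace(movie, masks$left)[keep]
  r <- mask_mean_trace(movie, masks$right)[keep]
  z <- outside_control_trace(movie, masks)[keep]
  partial_correlation(l, r, z)
}

# Control trace: mean over pixels outside the ROI. On the masked movie those
# pixels are NA, so the trace is recomputed from the stored raw outside
# means when available, else from the movie's non-ROI pixels.
outside_control_trace <- function(movie, masks) {
  tr <- attr(movie, "outside_trace")
  if (!is.null(tr)) return(tr)
  d <- dim(movie$data)
  m <- matrix(movie$data, d[1L] * d[2L], d[3L])
  sel <- m[which(masks$outside), , drop = FALSE]
  if (all(is.na(sel)))
    stop("outside-ROI pixels carry no data; attach an 'outside_trace' ",
         "attribute or supply an unmasked movie", call. = FALSE)
  colMeans(sel, na.rm = TRUE)
}

#' Seed-based partial-correlation map
#'
#' Partial correlation between the seed pixel's trace and every in-ROI
#' pixel's trace, controlled for the outside-ROI mean trace, with
#' motion-corrupted frames excluded. The map equals the residual-regression
#' formulation exactly: all traces are residualized against the control and
#' correlated in one matrix operation.
#'
#' @param movie a dF/F0 [movie_stack()].
#' @param seed `c(row, col)` of the seed pixel; must be inside the ROI.
#' @param masks a [roi_mask_set()].
#' @param motion optional `MotionTrace`.
#' @return A `CorrelationMap`: list with `r` (matrix, `NA` outside the ROI),
#'   `seed`, `control`, `frames_used`.
#' @export
seed_correlation_map <- function(movie, seed, masks, motion = NULL) {
  stopifnot(inherits(movie, "MovieStack"), length(seed) == 2L)
  roi <- in_roi_mask(masks)
  if (!roi[seed[1L], seed[2L]]) stop("seed outside ROI", call. = FALSE)
  keep <- frames_kept(n_frames(movie), motion)
  d <- dim(movie$data)
  m <- matrix(movie$data, d[1L] * d[2L], d[3L])[, keep, drop = FALSE]
  z <- outside_control_trace(movie, masks)[keep]
  idx <- which(roi)
  X <- t(m[idx, , drop = FALSE])          # frames x pixels
  X <- sweep(X, 2L, colMeans(X))
  if (sd(z) > 0) {
    zc <- z - mean(z)
    zc <- zc / sqrt(sum(zc^2))
    X <- X - zc %*% crossprod(zc, X)      # residualize against control
  } else message("constant control trace: plain Pearson map")
  nrm <- sqrt(colSums(X^2))
  si <- match((seed[2L] - 1L) * d[1L] + seed[1L], idx)
  rs <- as.vector(crossprod(X, X[, si])) / (nrm * nrm[si])
  rs[nrm == 0] <- NA_real_
  rs[si] <- 1
  rmap <- matrix(NA_real_, d[1L], d[2L])
  rmap[idx] <- rs
  structure(list(r = rmap, seed = seed, control = "outside-ROI mean",
                 frames_used = keep), class = "CorrelationMap")
}

#' @export
print.CorrelationMap <- function(x, ...) {
  cat(sprintf("<CorrelationMap> seed (%d, %d), %d frames, control: %s\n",
              x$seed[1L], x$seed[2L], length(x$frames_used), x$control))
  invisible(x)
}

#' Display a correlation map
#'
#' Renders the map with the display convention used throughout the analysis:
#' a jet-like palette with color limits `[-0.2, 1]`.
#'
#' @param x a `CorrelationMap`.
#' @param zlim color limits.
#' @param ... passed to [graphics::image()].
#' @export
plot.CorrelationMap <- function(x, zlim = c(-0.2, 1), ...) {
  jet <- grDevices::colorRampPalette(c("darkblue", "blue", "cyan", "green",
                                       "yellow", "orange", "red", "darkred"))
  v <- pmin(pmax(x$r, zlim[1L]), zlim[2L])
  graphics::image(t(v[nrow(v):1, ]), col = jet(256), zlim = zlim,
                  axes = FALSE, ...)
  graphics::box()
  invisible(x)
}

#' Build an evenly spaced seed lattice
#'
#' Near-square lattice of about `n` seeds covering the field, deterministic:
#' row/col counts are chosen to match the field aspect ratio with total
#' `>= n`, positions are centered in equal strips.
#'
#' @param dims `c(rows, cols)` of the (downsampled) field.
#' @param n requested seed count (default 1000).
#' @param masks optional [roi_mask_set()]; when supplied the `in_roi` column
#'   marks seeds inside a hemisphere.
#' @return A `SeedGrid` data frame: `row`, `col`, `grid_row`, `grid_col`,
#'   `in_roi`.
#' @export
build_seed_grid <- function(dims, n = 1000L, masks = NULL) {
  stopifnot(n >= 1L, length(dims) == 2L)
  if (n == 1L) {
    g <- data.frame(row = round((dims[1L] + 1) / 2),
                    col = round((dims[2L] + 1) / 2),
                    grid_row = 1L, grid_col = 1L)
  } else {
    nr <- max(1L, round(sqrt(n * dims[1L] / dims[2L])))
    nr <- min(nr, dims[1L])
    nc <- min(ceiling(n / nr), dims[2L])
    while (nr * nc < n && nr < dims[1L]) nr <- nr + 1L
    # a lattice denser than the pixel grid degenerates to every pixel
    rows <- pmin(dims[1L], pmax(1, ceiling((seq_len(nr) - 0.5) * dims[1L] / nr)))
    cols <- pmin(dims[2L], pmax(1, ceiling((seq_len(nc) - 0.5) * dims[2L] / nc)))
    g <- expand.grid(grid_row = seq_len(nr), grid_col = seq_len(nc))
    g$row <- rows[g$grid_row]; g$col <- cols[g$grid_col]
  }
  g$in_roi <- if (is.null(masks)) TRUE else
    in_roi_mask(masks)[cbind(g$row, g$col)]
  class(g) <- c("SeedGrid", class(g))
  g
}

#' Maximum neighborhood-mean correlation in a region
#'
#' Scores every pixel of the region by the mean correlation over its 5x5
#' neighborhood (in-region members only) and returns the best score - the
#' seed's maximum correlation in the region (SbBC when the region is the
#' contralateral symmetric ROI). Ties break to the smallest row, then
#' column.
#'
#' @param map a [seed_correlation_map()] result.
#' @param region logical matrix, e.g. the mirrored hemisphere ROI.
#' @param k neighborhood side (default 5).
#' @return List with `r_max` and `location` `c(row, col)`.
#' @export
max_symmetric_region_correlation <- function(map, region, k = 5L) {
  stopifnot(inherits(map, "CorrelationMap"), is.logical(region))
  if (!any(region)) stop("region is empty", call. = FALSE)
  v <- map$r
  v[!region] <- NA_real_
  sc <- box_mean(v, k)
  sc[!region] <- NA_real_
  best <- max(sc, na.rm = TRUE)
  loc <- which(sc == best, arr.ind = TRUE)
  loc <- loc[order(loc[, 1L], loc[, 2L]), , drop = FALSE][1L, ]
  list(r_max = best, location = c(row = loc[[1L]], col = loc[[2L]]))
}

#' Morphology of a high-correlation region
#'
#' Thresholds the map at `r > threshold` (0.95 by default), takes the
#' connected component containing the seed, approximates it as an ellipse by
#' second central moments, and reports the aspect ratio `a/b` (eccentricity)
#' and the component area normalized by the hemisphere area.
#'
#' @param map a [seed_correlation_map()] result.
#' @param hemisphere logical matrix of the seed's hemisphere.
#' @param threshold correlation threshold.
#' @return A `RegionProps` list: `eccentricity`, `proportion`, `area_px`,
#'   `threshold`.
#' @export
correlation_region_properties <- function(map, hemisphere, threshold = 0.95) {
  stopifnot(inherits(map, "CorrelationMap"))
  bw <- !is.na(map$r) & map$r > threshold
  lab <- EBImage::bwlabel(bw + 0)
  id <- lab[map$seed[1L], map$seed[2L]]
  if (id == 0) stop("no suprathreshold component contains the seed",
                    call. = FALSE)
  px <- which(lab == id, arr.ind = TRUE)
  if (nrow(px) < 2L) stop("suprathreshold component degenerate", call. = FALSE)
  # second central moments with the 1/12 per-pixel term (regionprops
  # convention), eigen-decomposed to ellipse axes
  cv <- stats::cov(px) * (nrow(px) - 1) / nrow(px) + diag(1 / 12, 2L)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  structure(list(eccentricity = sqrt(ev[1L] / ev[2L]),
                 proportion = nrow(px) / sum(hemisphere),
                 area_px = nrow(px), threshold = threshold),
            class = "RegionProps")
}

# Number of transverse bands in the thresholded ipsilateral map: a column of
# the hemisphere is active when any of its pixels is suprathreshold; bands
# are runs of consecutive active columns.
count_bands <- function(map, hemisphere, threshold = 0.6) {
  v <- map$r
  v[!hemisphere | is.na(v)] <- -Inf
  cols <- which(colSums(hemisphere) > 0)
  active <- apply(v[, cols, drop = FALSE], 2L, max) > threshold
  r <- rle(active)
  sum(r$values)
}

#' Select low/mid/high representative seeds
#'
#' Walks the seed-grid column nearest the hemisphere centre row of the left
#' IC from medial to lateral: the low-frequency seed is the most medial seed
#' whose ipsilateral suprathreshold pattern shows a single band; the mid
#' seed lies 3 grid steps lateral at the first position showing a pair of
#' bands, and the high seed 3 further steps (again at the first dual-band
#' position). Slots with no qualifying seed are returned as `NULL`.
#'
#' @param movie a dF/F0 [movie_stack()].
#' @param masks a [roi_mask_set()].
#' @param motion optional `MotionTrace`.
#' @param grid optional [build_seed_grid()]; defaults to a 1000-seed lattice.
#' @param band_threshold suprathreshold level defining a visible band.
#' @return List with `low`, `mid`, `high` (each `c(row, col)` or `NULL`) and
#'   `band_counts` along the scanned seed column.
#' @export
select_representative_seeds <- function(movie, masks, motion = NULL,
                                        grid = NULL, band_threshold = 0.6) {
  d <- dim(movie$data)
  grid <- grid %||% build_seed_grid(d[1:2], 1000L, masks)
  mid <- find_midline(masks)
  cl <- which(masks$left, arr.ind = TRUE)
  ctr_row <- mean(range(cl[, 1L]))
  cand <- grid[grid$in_roi & masks$left[cbind(grid$row, grid$col)], ,
               drop = FALSE]
  if (nrow(cand) == 0L) stop("no grid seeds inside the left hemisphere",
                             call. = FALSE)
  row_pick <- cand$grid_row[which.min(abs(cand$row - ctr_row))]
  lane <- cand[cand$grid_row == row_pick, , drop = FALSE]
  lane <- lane[order(abs(lane$col - mid)), , drop = FALSE]  # medial->lateral
  bands <- integer(nrow(lane))
  mapfor <- function(i) seed_correlation_map(movie, c(lane$row[i], lane$col[i]),
                                             masks, motion)
  for (i in seq_len(nrow(lane)))
    bands[i] <- count_bands(mapfor(i), masks$left, band_threshold)
  pick_from <- function(start, want) {
    i <- start
    while (i <= length(bands)) {
      if (bands[i] == want) return(i)
      i <- i + 1L
    }
    NA_integer_
  }
  i_low <- pick_from(1L, 1L)
  i_mid <- if (!is.na(i_low)) pick_from(i_low + 3L, 2L) else NA_integer_
  i_high <- if (!is.na(i_mid)) pick_from(i_mid + 3L, 2L) else NA_integer_
  as_seed <- function(i) if (is.na(i)) NULL else
    c(row = lane$row[i], col = lane$col[i])
  list(low = as_seed(i_low), mid = as_seed(i_mid), high = as_seed(i_high),
       band_counts = bands)
}

#' Seed-based bilateral correlation statistics
#'
#' For each representative seed, the SbBC is the maximum 5x5
#' neighborhood-mean correlation inside the symmetric contralateral ROI (the
#' seed's hemisphere mask reflected across the detected midline). The
#' averaged SbBC is the mean of the low/mid/high values; the global
#' bilateral correlation is reported alongside.
#'
#' @param movie a dF/F0 [movie_stack()].
#' @param masks a [roi_mask_set()].
#' @param motion optional `MotionTrace`.
#' @param seeds list with `low`, `mid`, `high` seeds (e.g. from
#'   [select_representative_seeds()]); `NULL` slots give `NA`.
#' @return A `BilateralStats` list: `global_r`, `sbbc` (named low/mid/high),
#'   `sbbc_avg`, `max_locations`.
#' @export
bilateral_stats <- function(movie, masks, motion = NULL, seeds) {
  mid <- find_midline(masks)
  vals <- c(low = NA_real_, mid = NA_real_, high = NA_real_)
  locs <- list()
  for (nm in names(vals)) {
    sd_ <- seeds[[nm]]
    if (is.null(sd_)) next
    cmap <- seed_correlation_map(movie, sd_, masks, motion)
    hemi <- if (masks$left[sd_[1L], sd_[2L]]) masks$left else masks$right
    contra <- mirror_mask(hemi, mid)
    mx <- max_symmetric_region_correlation(cmap, contra)
    vals[nm] <- mx$r_max
    locs[[nm]] <- mx$location
  }
  structure(list(global_r = global_bilateral_correlation(movie, masks, motion),
                 sbbc = vals, sbbc_avg = mean(vals, na.rm = FALSE),
                 max_locations = locs), class = "BilateralStats")
}

#' @export
print.BilateralStats <- function(x, ...) {
  cat(sprintf("<BilateralStats> global r = %.4f | SbBC low %.4f mid %.4f high %.4f | avg %.4f\n",
              x$global_r, x$sbbc["low"], x$sbbc["mid"], x$sbbc["high"],
              x$sbbc_avg))
  invisible(x)
}
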