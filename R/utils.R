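# Internal numeric helpers shared across modules.

# Evaluate expr with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards. All package randomness funnels through this.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Clipped-window box mean of a matrix. Windows are k x k, truncated at the
# matrix border; NA entries (out-of-ROI pixels) are excluded from both the
# sum and the count, so border/ROI-edge means use in-window members only.
box_mean <- function(x, k = 5L) {
  stopifnot(is.matrix(x), k >= 1L, k %% 2L == 1L)
  h <- (k - 1L) %/% 2L
  ok <- !is.na(x)
  v <- x
  v[!ok] <- 0
  sums <- .box_sum(v, h)
  cnts <- .box_sum(ok + 0, h)
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  out
}

# Summed-area-table box sum with half-width h, clipped at borders.
.box_sum <- function(v, h) {
  nr <- nrow(v); nc <- ncol(v)
  s <- apply(v, 2L, cumsum)
  s <- rbind(0, s)
  lo <- pmax(1L, seq_len(nr) - h); hi <- pmin(nr, seq_len(nr) + h)
  v2 <- s[hi + 1L, , drop = FALSE] - s[lo, , drop = FALSE]
  s2 <- t(apply(v2, 1L, cumsum))
  if (nc == 1L) s2 <- matrix(v2, nrow = nr)  # apply() drops dims for nc == 1
  s2 <- cbind(0, s2)
  lo <- pmax(1L, seq_len(nc) - h); hi <- pmin(nc, seq_len(nc) + h)
  s2[, hi + 1L, drop = FALSE] - s2[, lo, drop = FALSE]
}

# Normalized Gaussian kernel truncated at `truncate` sigma.
gaussian_kernel <- function(sigma = 1, truncate = 4) {
  stopifnot(sigma > 0)
  r <- ceiling(truncate * sigma)
  g <- dnorm(seq(-r, r), sd = sigma)
  k <- outer(g, g)
  k / sum(k)
}

# Indices of 1-D local maxima; plateaus count once at their first index;
# runs touching either end of the vector are not maxima.
local_maxima_1d <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  r <- rle(v)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-k]))
  inner <- 2:(k - 1L)
  is_max <- r$values[inner] > r$values[inner - 1L] &
    r$values[inner] > r$values[inner + 1L]
  starts[inner][is_max]
}

# Full width at half maximum around a local peak, by linear interpolation of
# the half-crossings on each side. The half level sits midway between the
# peak and `baseline` (default 0); percentile-based dF/F0 normalization
# leaves a small positive pedestal, so callers pass the map's event-free
# level to keep widths unbiased. A side whose flank starts rising again
# before reaching half (a merged neighboring peak) is clipped at the valley;
# the valley stop only engages once the flank has dropped 20% of the
# prominence, so slope~0 ripples at the summit cannot truncate the walk.
# Sides clipped by the record edge are mirrored from the measurable side and
# the event flagged "edge".
fwhm_1d <- function(v, ipk, baseline = 0) {
  n <- length(v)
  half <- baseline + (v[ipk] - baseline) / 2
  deep <- baseline + 0.8 * (v[ipk] - baseline)
  right <- NA_real_; left <- NA_real_
  i <- ipk
  while (i < n && v[i + 1L] >= half) {
    if (v[i + 1L] > v[i] && v[i] <= deep) break
    i <- i + 1L
  }
  if (i < n) {
    right <- if (v[i + 1L] < half)
      i + (v[i] - half) / (v[i] - v[i + 1L]) else i
  }
  i <- ipk
  while (i > 1L && v[i - 1L] >= half) {
    if (v[i - 1L] > v[i] && v[i] <= deep) break
    i <- i - 1L
  }
  if (i > 1L) {
    left <- if (v[i - 1L] < half)
      i - (v[i] - half) / (v[i] - v[i - 1L]) else i
  }
  edge <- is.na(left) || is.na(right)
  if (is.na(left) && is.na(right)) {
    return(list(width = NA_real_, lo = 1, hi = n, edge = TRUE))
  }
  if (is.na(left)) left <- ipk - (right - ipk)
  if (is.na(right)) right <- ipk + (ipk - left)
  list(width = right - left, lo = left, hi = right, edge = edge)
}

# Rigid translation of a matrix by (dy, dx) pixels (content moves towards
# larger row/col for positive shifts), bilinear interpolation, edge-replicated
# boundary fill.
shift_frame <- function(x, dy, dx) {
  stopifnot(is.matrix(x), is.finite(dy), is.finite(dx))
  nr <- nrow(x); nc <- ncol(x)
  ys <- seq_len(nr) - dy
  xs <- seq_len(nc) - dx
  y0 <- pmin(pmax(floor(ys), 1L), nr); y1 <- pmin(y0 + 1L, nr)
  x0 <- pmin(pmax(floor(xs), 1L), nc); x1 <- pmin(x0 + 1L, nc)
  fy <- pmin(pmax(ys - y0, 0), 1)
  fx <- pmin(pmax(xs - x0, 0), 1)
  a <- x[y0, x0, drop = FALSE] * (1 - fy) + x[y1, x0, drop = FALSE] * fy
  b <- x[y0, x1, drop = FALSE] * (1 - fy) + x[y1, x1, drop = FALSE] * fy
  a * rep(1 - fx, each = nr) + b * rep(fx, each = nr)
}

# Per-pixel quantile (linear interpolation between order statistics,
# stats::quantile type 7) along the third dimension of a movie array.
pixel_quantile <- function(arr, p) {
  d <- dim(arr)
  m <- matrix(arr, d[1L] * d[2L], d[3L])
  apply(m, 1L, function(v) {
    if (anyNA(v)) return(NA_real_)
    unname(quantile(v, p, type = 7))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
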