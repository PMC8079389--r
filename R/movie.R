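#' Fluorescence movie container
#'
#' A `MovieStack` wraps a `row x col x frame` numeric array together with its
#' acquisition frame rate and a provenance record of the preprocessing steps
#' already applied to it. Out-of-ROI pixels are encoded as `NA` once a mask
#' has been applied; all downstream statistics skip them.
#'
#' @param data numeric 3-D array, dimensions `(rows, cols, frames)`.
#' @param frame_rate acquisition rate in Hz (default 10).
#' @param steps character vector of preprocessing steps already applied.
#' @return An object of class `MovieStack`.
#' @export
movie_stack <- function(data, frame_rate = 10, steps = character()) {
  stopifnot(is.array(data), length(dim(data)) == 3L, frame_rate > 0)
  structure(list(data = data, frame_rate = frame_rate, steps = steps),
            class = "MovieStack")
}

#' @export
print.MovieStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<MovieStack> %d x %d px, %d frames @ %g Hz (%.1f s)\n",
              d[1], d[2], d[3], x$frame_rate, d[3] / x$frame_rate))
  if (length(x$steps))
    cat("  steps applied:", paste(x$steps, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.MovieStack <- function(x) dim(x$data)

n_frames <- function(movie) dim(movie$data)[3L]

# Guard against running a preprocessing step twice (provenance audit).
mark_step <- function(movie, step) {
  if (step %in% movie$steps)
    stop("preprocessing step '", step, "' has already been applied", call. = FALSE)
  movie$steps <- c(movie$steps, step)
  movie
}

#' Labeled hemisphere / background masks
#'
#' Bundles the left-IC, right-IC and outside-ROI (background) masks used
#' throughout the analysis. The outside region provides the control regressor
#' for partial correlations. Additional labeled regions (e.g. cortical
#' windows) may be supplied through `extra`.
#'
#' @param left,right logical matrices marking the two hemisphere ROIs.
#' @param outside logical matrix marking the background region used as the
#'   partial-correlation control; defaults to every pixel in neither
#'   hemisphere.
#' @param extra optional named list of further logical masks.
#' @return An object of class `RoiMaskSet`.
#' @export
roi_mask_set <- function(left, right, outside = NULL, extra = list()) {
  stopifnot(is.matrix(left), is.matrix(right), is.logical(left),
            is.logical(right), all(dim(left) == dim(right)))
  if (any(left & right)) stop("hemisphere masks overlap", call. = FALSE)
  if (is.null(outside)) outside <- !(left | right)
  stopifnot(is.logical(outside), all(dim(outside) == dim(left)))
  if (any(outside & (left | right)))
    stop("outside mask overlaps a hemisphere mask", call. = FALSE)
  structure(list(left = left, right = right, outside = outside, extra = extra),
            class = "RoiMaskSet")
}

#' @export
print.RoiMaskSet <- function(x, ...) {
  cat(sprintf("<RoiMaskSet> %d x %d px | left %d px, right %d px, outside %d px\n",
              nrow(x$left), ncol(x$left), sum(x$left), sum(x$right),
              sum(x$outside)))
  invisible(x)
}

in_roi_mask <- function(masks) masks$left | masks$right

#' Locate the bilateral midline of a mask set
#'
#' Finds the vertical axis about which the combined hemisphere masks are most
#' nearly mirror-symmetric. The axis is returned as a (possibly half-integer)
#' column coordinate: column `c` reflects to `2 * midline - c`.
#'
#' @param masks a [roi_mask_set()].
#' @return Numeric scalar, the mirror-axis column coordinate.
#' @export
find_midline <- function(masks) {
  comb <- in_roi_mask(masks)
  nc <- ncol(comb)
  cand <- seq(1, nc, by = 0.5)
  score <- vapply(cand, function(a) {
    refl <- round(2 * a - which(comb, arr.ind = TRUE)[, 2L])
    px <- which(comb, arr.ind = TRUE)
    ok <- refl >= 1L & refl <= nc
    if (!any(ok)) return(0)
    sum(comb[cbind(px[ok, 1L], refl[ok])]) / nrow(px)
  }, numeric(1))
  best <- which(score == max(score))
  # ties: pick the candidate closest to the field centre
  cand[best[which.min(abs(cand[best] - (nc + 1) / 2))]]
}

#' Reflect a mask or pixel location across the midline
#'
#' @param mask logical matrix to reflect.
#' @param midline mirror-axis column coordinate from [find_midline()].
#' @return The reflected logical matrix.
#' @export
mirror_mask <- function(mask, midline) {
  nc <- ncol(mask)
  out <- matrix(FALSE, nrow(mask), nc)
  px <- which(mask, arr.ind = TRUE)
  if (nrow(px) == 0L) return(out)
  refl <- round(2 * midline - px[, 2L])
  ok <- refl >= 1L & refl <= nc
  out[cbind(px[ok, 1L], refl[ok])] <- TRUE
  out
}

# TRUE when left and right masks are exact mirror images about the midline.
masks_mirror_symmetric <- function(masks, midline = find_midline(masks)) {
  identical(mirror_mask(masks$left, midline), masks$right)
}

#' Read / write multi-page TIFF movies
#'
#' Movies travel as 32-bit float multi-page TIFF, one page per frame; label
#' masks as single-page integer TIFF (0 = outside, 1 = left, 2 = right).
#'
#' @param path file path.
#' @param frame_rate frame rate to stamp on the returned [movie_stack()].
#' @return `read_movie_tiff` returns a `MovieStack`.
#' @export
read_movie_tiff <- function(path, frame_rate = 10) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(unlist(pages), dim = c(dim(pages[[1L]])[1:2], length(pages)))
  movie_stack(arr, frame_rate = frame_rate)
}

#' @rdname read_movie_tiff
#' @param movie a `MovieStack` to write.
#' @export
write_movie_tiff <- function(movie, path) {
  d <- dim(movie$data)
  pages <- lapply(seq_len(d[3L]), function(i) {
    fr <- movie$data[, , i]
    fr[is.na(fr)] <- 0
    fr
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname read_movie_tiff
#' @param masks a `RoiMaskSet` to write as a label image.
#' @export
write_mask_tiff <- function(masks, path) {
  lab <- matrix(0, nrow(masks$left), ncol(masks$left))
  lab[masks$left] <- 1; lab[masks$right] <- 2
  tiff::writeTIFF(lab / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname read_movie_tiff
#' @export
read_mask_tiff <- function(path) {
  lab <- round(tiff::readTIFF(path) * 255)
  roi_mask_set(left = lab == 1, right = lab == 2)
}
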