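#' Gaussian affinity matrix over pixel activity
#'
#' Projects pixels (rows of `traces`) onto a weighted graph with
#' `W_ij = exp(-d_ij^2 / sigma^2)`, where `d` is the Euclidean distance
#' between activity traces and the kernel scale adapts to the data
#' landscape: `sigma = 2 * sd` of all pairwise distances.
#'
#' @param traces numeric matrix, one row per pixel, one column per frame.
#' @return The affinity matrix with attribute `sigma`.
#' @export
build_affinity <- function(traces) {
  stopifnot(is.matrix(traces), nrow(traces) >= 3L, all(is.finite(traces)))
  d <- stats::dist(traces)
  sigma <- 2 * stats::sd(d)
  if (!is.finite(sigma) || sigma == 0)
    stop("all traces identical: kernel scale is zero", call. = FALSE)
  W <- exp(-as.matrix(d)^2 / sigma^2)
  dimnames(W) <- NULL
  diag(W) <- 1
  attr(W, "sigma") <- sigma
  W
}

#' Eigendecomposition of the Markov matrix of an affinity graph
#'
#' Row-normalizes `W` into the random-walk transition matrix
#' `P = D^{-1} W` and returns its eigenpairs, sorted by decreasing
#' eigenvalue. The computation goes through the symmetric conjugate
#' `D^{-1/2} W D^{-1/2}`, so eigenvalues are real; the leading pair is
#' `lambda = 1` with a constant eigenvector.
#'
#' @param W nonnegative symmetric affinity matrix.
#' @return List with `values` and `vectors` (columns, right eigenvectors of
#'   `P`).
#' @export
markov_eigendecomposition <- function(W) {
  stopifnot(is.matrix(W), isSymmetric(unname(W), tol = 1e-10), all(W >= 0))
  rs <- rowSums(W)
  if (any(rs == 0)) stop("zero row sum in affinity matrix", call. = FALSE)
  dhalf <- 1 / sqrt(rs)
  S <- W * (dhalf %o% dhalf)
  e <- eigen(S, symmetric = TRUE)
  vec <- e$vectors * dhalf               # back-transform to eigenvectors of P
  # fix an overall sign per vector for determinism
  for (j in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  list(values = e$values, vectors = vec)
}

#' Three-dimensional diffusion embedding
#'
#' Projects pixels to 3-D diffusion coordinates
#' `psi_k = lambda_{k+1}^t * v_{k+1}`, `k = 1..3`, skipping the trivial
#' constant eigenpair.
#'
#' @param eig result of [markov_eigendecomposition()].
#' @param t diffusion time (default 1).
#' @return A `DiffusionEmbedding`: list with `coords` (`n x 3`), `values`,
#'   `t`.
#' @export
embed_3d <- function(eig, t = 1) {
  if (length(eig$values) < 4L)
    stop("need at least 4 eigenpairs for a 3-D embedding", call. = FALSE)
  ix <- 2:4
  co <- sweep(eig$vectors[, ix, drop = FALSE], 2L, eig$values[ix]^t, `*`)
  colnames(co) <- paste0("psi", 1:3)
  structure(list(coords = co, values = eig$values, t = t),
            class = "DiffusionEmbedding")
}

#' Diffusion-map embedding of a movie's in-ROI pixels
#'
#' Convenience chain: extract in-ROI pixel traces, build the Gaussian
#' affinity, decompose the Markov matrix, and embed in 3-D. Intended for the
#' downsampled field (a dense eigensolver is used; pixel counts above
#' `max_pixels` are refused).
#'
#' @param movie a dF/F0 [movie_stack()].
#' @param masks a [roi_mask_set()].
#' @param t diffusion time.
#' @param max_pixels guard for the dense solver.
#' @return A `DiffusionEmbedding` with an extra `pixels` data frame mapping
#'   rows of `coords` back to `(row, col)` on the field, and `sigma`.
#' @export
diffusion_map <- function(movie, masks, t = 1, max_pixels = 3000L) {
  roi <- in_roi_mask(masks)
  idx <- which(roi)
  if (length(idx) > max_pixels)
    stop("too many pixels for the dense eigensolver; downsample first",
         call. = FALSE)
  d <- dim(movie$data)
  m <- matrix(movie$data, d[1L] * d[2L], d[3L])
  W <- build_affinity(m[idx, , drop = FALSE])
  eig <- markov_eigendecomposition(W)
  emb <- embed_3d(eig, t = t)
  rc <- arrayInd(idx, d[1:2])
  emb$pixels <- data.frame(row = rc[, 1L], col = rc[, 2L])
  emb$sigma <- attr(W, "sigma")
  emb
}

#' @export
print.DiffusionEmbedding <- function(x, ...) {
  cat(sprintf("<DiffusionEmbedding> %d pixels, t = %g, lambda_2..4 = %s\n",
              nrow(x$coords), x$t,
              paste(sprintf("%.4f", x$values[2:4]), collapse = ", ")))
  invisible(x)
}
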