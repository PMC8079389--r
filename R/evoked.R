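#' Build the tone-stimulation protocol
#'
#' SAM-tone protocol: carrier frequencies from 4 to 32 kHz in half-octave
#' steps (7 frequencies), sound levels from 96 down to 8 dB SPL in 8-dB
#' decrements (12 levels), giving 84 frequency-SPL combinations. Each trial
#' lasts 5 s at 10 Hz (1 s pre-stimulus idle, 0.5 s stimulation, 3.5 s
#' post-stimulus idle), i.e. exactly 50 camera frames; a session presents
#' every combination once in seeded random order (4200 frames).
#'
#' @param seed RNG seed for the per-session trial orders.
#' @param n_sessions number of per-session orders to draw.
#' @param frequencies_khz,levels_db override the default stimulus sets.
#' @param frame_rate camera rate, Hz.
#' @param pre_s,stim_s,post_s trial layout, s.
#' @return A `StimulusProtocol` list: `frequencies_khz`, `levels_db`,
#'   `combinations` (data frame), `frames_per_trial`, `frames_per_session`,
#'   `session_orders`, layout fields, `sam` metadata (modulation depth 1,
#'   10 Hz).
#' @export
build_stimulus_protocol <- function(seed = 1L, n_sessions = 1L,
                                    frequencies_khz = NULL, levels_db = NULL,
                                    frame_rate = 10, pre_s = 1, stim_s = 0.5,
                                    post_s = 3.5) {
  freqs <- frequencies_khz %||% (4 * 2^seq(0, 3, by = 0.5))
  levels <- levels_db %||% seq(96, 8, by = -8)
  combos <- expand.grid(frequency_khz = freqs, spl_db = levels,
                        KEEP.OUT.ATTRS = FALSE)
  combos <- combos[order(combos$frequency_khz, -combos$spl_db), ]
  rownames(combos) <- NULL
  fpt <- as.integer(round((pre_s + stim_s + post_s) * frame_rate))
  orders <- with_seed(seed, lapply(seq_len(n_sessions), function(s)
    sample.int(nrow(combos))))
  structure(list(frequencies_khz = freqs, levels_db = levels,
                 combinations = combos,
                 frames_per_trial = fpt,
                 frames_per_session = fpt * nrow(combos),
                 session_orders = orders,
                 frame_rate = frame_rate, pre_s = pre_s, stim_s = stim_s,
                 post_s = post_s,
                 sam = list(modulation_depth = 1, modulation_hz = 10),
                 seed = seed),
            class = "StimulusProtocol")
}

#' @export
print.StimulusProtocol <- function(x, ...) {
  cat(sprintf(paste0("<StimulusProtocol> %d frequencies x %d levels = %d ",
                     "combinations | %d frames/trial, %d frames/session\n"),
              length(x$frequencies_khz), length(x$levels_db),
              nrow(x$combinations), x$frames_per_trial, x$frames_per_session))
  invisible(x)
}

combo_key <- function(f, l) sprintf("%.3fkHz_%gdB", f, l)

#' Average trials into per-condition mean movies
#'
#' Sorts trials from all sessions into frequency-SPL groups and computes the
#' frame-wise mean movie of each group (the response tensor).
#'
#' @param sessions list of sessions, each a list with `movie` (a
#'   [movie_stack()]) and `log` (trial log with `frequency_khz`, `spl_db`,
#'   `start_frame`).
#' @param protocol the [build_stimulus_protocol()] the sessions follow.
#' @return A `ResponseTensor`: list with `entries` (named list of
#'   `rows x cols x frames_per_trial` arrays), `counts`, `combinations`,
#'   `frame_rate`.
#' @export
average_trials <- function(sessions, protocol) {
  stopifnot(inherits(protocol, "StimulusProtocol"), length(sessions) >= 1L)
  fpt <- protocol$frames_per_trial
  combos <- protocol$combinations
  keys <- combo_key(combos$frequency_khz, combos$spl_db)
  sums <- vector("list", nrow(combos)); names(sums) <- keys
  counts <- integer(nrow(combos)); names(counts) <- keys
  for (s in sessions) {
    log <- s$log
    starts <- sort(log$start_frame)
    if (length(starts) > 1L && any(diff(starts) < fpt))
      stop("trial frame windows overlap", call. = FALSE)
    for (i in seq_len(nrow(log))) {
      k <- combo_key(log$frequency_khz[i], log$spl_db[i])
      if (!k %in% keys) stop("trial condition ", k, " not in protocol",
                             call. = FALSE)
      a <- s$movie$data[, , log$start_frame[i] + seq_len(fpt) - 1L,
                        drop = FALSE]
      sums[[k]] <- if (is.null(sums[[k]])) a else sums[[k]] + a
      counts[k] <- counts[k] + 1L
    }
  }
  zero <- names(counts)[counts == 0L]
  if (length(zero))
    stop("no trials for combination(s): ", paste(zero, collapse = ", "),
         call. = FALSE)
  entries <- mapply(function(a, n) a / n, sums, counts, SIMPLIFY = FALSE)
  structure(list(entries = entries, counts = counts, combinations = combos,
                 frame_rate = protocol$frame_rate), class = "ResponseTensor")
}

#' Normalize a response tensor to dF/F0
#'
#' Per pixel, `F0` is the mean over the pre-stimulus baseline frames
#' (default the first 10) of the trial-averaged movie; entries become
#' `(F - F0) / F0`.
#'
#' @param tensor a [average_trials()] result.
#' @param baseline_frames frame indices (1-based) of the baseline window.
#' @return The normalized `ResponseTensor`.
#' @export
evoked_dff <- function(tensor, baseline_frames = 1:10) {
  stopifnot(inherits(tensor, "ResponseTensor"))
  tensor$entries <- lapply(tensor$entries, function(a) {
    d <- dim(a)
    if (d[3L] <= max(baseline_frames))
      stop("entry shorter than the baseline window", call. = FALSE)
    f0 <- rowMeans(a[, , baseline_frames, drop = FALSE], dims = 2L)
    if (any(f0 <= 0, na.rm = TRUE))
      stop("nonpositive baseline F0", call. = FALSE)
    (a - as.vector(f0)) / as.vector(f0)
  })
  tensor$normalized <- TRUE
  tensor
}

#' Pooled population response curve of one condition
#'
#' Finds the pixel with the maximum dF/F0 during the stimulation window
#' (frames 11-15 of the trial-averaged entry), computes the plain Pearson
#' correlation of every pixel's trace with that pixel's trace, pools all
#' pixels above the high-correlation threshold (0.997), and returns their
#' mean trace.
#'
#' @param entry one dF/F0 entry of a [evoked_dff()] tensor (3-D array).
#' @param corr_threshold pooling correlation level.
#' @param search_frames stimulation window used to find the max pixel.
#' @return List with `curve` (length `n_frames`), `seed_px` `c(row, col)`,
#'   `region` (logical matrix), `n_pooled`.
#' @export
pooled_response_curve <- function(entry, corr_threshold = 0.997,
                                  search_frames = 11:15) {
  d <- dim(entry)
  stopifnot(length(d) == 3L, max(search_frames) <= d[3L])
  win <- entry[, , search_frames, drop = FALSE]
  pkmax <- apply(win, c(1L, 2L), max)
  pkmax[is.na(pkmax)] <- -Inf
  best <- which(pkmax == max(pkmax), arr.ind = TRUE)[1L, ]
  m <- matrix(entry, d[1L] * d[2L], d[3L])
  seed_i <- (best[2L] - 1L) * d[1L] + best[1L]
  rs <- suppressWarnings(cor(t(m), m[seed_i, ]))
  region <- matrix(!is.na(rs) & rs > corr_threshold, d[1L], d[2L])
  region[best[1L], best[2L]] <- TRUE     # seed has r = 1 by construction
  curve <- colMeans(m[which(region), , drop = FALSE], na.rm = TRUE)
  list(curve = curve, seed_px = c(row = best[[1L]], col = best[[2L]]),
       region = region, n_pooled = sum(region))
}

#' Call the auditory threshold at one frequency
#'
#' A level is "responding" when its pooled response curve crosses the
#' criterion (2\% dF/F0) anywhere in the response window (frames 11-20).
#' The threshold is the lowest responding SPL; when no level responds the
#' sentinel `NA` is returned. Non-monotone responding patterns are called by
#' the same literal rule, with a warning.
#'
#' @param curves numeric matrix, one row per level (ordered as `levels_db`),
#'   one column per frame.
#' @param levels_db SPLs corresponding to the rows.
#' @param criterion response criterion, dF/F0.
#' @param window response window, frame indices.
#' @return List with `threshold_db` (`NA` = no response), `responding`
#'   (logical per level), `peaks` (max curve value in the window per level).
#' @export
determine_threshold <- function(curves, levels_db, criterion = 0.02,
                                window = 11:20) {
  stopifnot(is.matrix(curves), nrow(curves) == length(levels_db))
  peaks <- apply(curves[, window, drop = FALSE], 1L, max)
  responding <- peaks >= criterion
  thr <- if (any(responding)) min(levels_db[responding]) else NA_real_
  if (any(responding)) {
    above <- levels_db >= thr
    if (!all(responding[above]))
      warning("non-monotone responding pattern across SPL levels")
  }
  list(threshold_db = thr, responding = responding, peaks = peaks)
}

#' Mean response image of one condition
#'
#' Per-pixel mean of the dF/F0 frames during the stimulation window
#' (frames 11-15).
#'
#' @param entry one dF/F0 entry (3-D array).
#' @param frames averaging window.
#' @return A 2-D image matrix.
#' @export
response_image <- function(entry, frames = 11:15) {
  stopifnot(length(dim(entry)) == 3L, max(frames) <= dim(entry)[3L])
  rowMeans(entry[, , frames, drop = FALSE], dims = 2L)
}

#' Per-frequency auditory-threshold table
#'
#' Runs the pooled-curve extraction and threshold call for every frequency
#' of the protocol.
#'
#' @param tensor a dF/F0 [evoked_dff()] tensor.
#' @param protocol the matching [build_stimulus_protocol()].
#' @param criterion response criterion, dF/F0.
#' @param window response window (frames).
#' @param corr_threshold pooling correlation level.
#' @param search_frames stimulation window for the max pixel.
#' @return A `ThresholdTable` data frame: `frequency_khz`, `threshold_db`
#'   (`NA` = no response), plus an attribute `peaks` (frequency x level
#'   matrix of window maxima).
#' @export
threshold_table <- function(tensor, protocol, criterion = 0.02,
                            window = 11:20, corr_threshold = 0.997,
                            search_frames = 11:15) {
  stopifnot(inherits(tensor, "ResponseTensor"), isTRUE(tensor$normalized))
  freqs <- protocol$frequencies_khz
  levels <- protocol$levels_db
  peaks <- matrix(NA_real_, length(freqs), length(levels),
                  dimnames = list(sprintf("%.2f", freqs), levels))
  thr <- rep(NA_real_, length(freqs))
  for (fi in seq_along(freqs)) {
    curves <- t(vapply(levels, function(l) {
      pooled_response_curve(tensor$entries[[combo_key(freqs[fi], l)]],
                            corr_threshold, search_frames)$curve
    }, numeric(dim(tensor$entries[[1L]])[3L])))
    res <- determine_threshold(curves, levels, criterion, window)
    thr[fi] <- res$threshold_db
    peaks[fi, ] <- res$peaks
  }
  out <- data.frame(frequency_khz = freqs, threshold_db = thr,
                    no_response = is.na(thr))
  attr(out, "peaks") <- peaks
  class(out) <- c("ThresholdTable", class(out))
  out
}
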