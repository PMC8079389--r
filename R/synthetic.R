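#' Configuration for the synthetic spontaneous-activity generator
#'
#' Describes a seeded synthetic wide-field movie of bilateral band-shaped
#' spontaneous calcium events in the developing inferior colliculus. Two
#' mirror-symmetric elliptical hemisphere masks sit either side of a vertical
#' midline; the tonotopic axis runs horizontally within each hemisphere from
#' medial (next to the midline, coordinate `p = 0`) to lateral (`p = 1`).
#' Events at `p < p_split` render one band; events at `p >= p_split` render a
#' pair of bands at the reversal-symmetric positions within the hemisphere,
#' emulating the tonotopic reversal of the IC dorsal surface. With
#' probability `coupling` an event is mirrored at the homologous tonotopic
#' position of the other hemisphere.
#'
#' @param frame_rate acquisition rate, Hz.
#' @param duration_s record length, s.
#' @param fov `c(rows, cols)` field-of-view size in px; `cols` must be even so
#'   the two hemisphere masks can be exact mirror images.
#' @param hemi_semiaxes `c(row, col)` semi-axes of each elliptical hemisphere
#'   mask, px.
#' @param hemi_col_center distance of each ellipse centre from the midline, px.
#' @param event_rate events per minute per hemisphere (Poisson).
#' @param coupling probability in `[0, 1]` that an event is mirrored
#'   contralaterally.
#' @param mirror_time_jitter SD of the mirrored partner's frame offset, frames.
#' @param mirror_pos_jitter SD of the partner's tonotopic offset, fraction of
#'   the tonotopic extent.
#' @param band_sd Gaussian SD of the band profile across the tonotopic axis,
#'   fraction of the tonotopic extent (spatial FWHM = 2.355 * band_sd *
#'   extent).
#' @param p_split tonotopic coordinate separating medial single-band from
#'   lateral dual-band events.
#' @param amp_meanlog,amp_sdlog lognormal peak-amplitude parameters, dF/F0
#'   units.
#' @param tau_cal_s calcium indicator decay constant, s (GCaMP6s-like).
#' @param rise_frames linear rise time, frames.
#' @param baseline resting fluorescence, a.u.
#' @param outside_baseline resting fluorescence outside the ROI, a.u.
#' @param noise_sd i.i.d. additive noise SD, a.u.
#' @param bleach_tau_s photobleaching time constant, s (`NULL` = no bleach);
#'   frame `t` is multiplied by the single-exponential trend
#'   `exp(-t / tau_b)`.
#' @param motion_sd SD of per-frame rigid shifts, px (0 = static).
#' @param background_amp amplitude of a slow global background fluctuation,
#'   a.u., added everywhere including outside the ROI (exercises the
#'   partial-correlation control).
#' @param seed RNG seed; same config + seed gives a bit-identical movie.
#' @return A list of class `SyntheticSpontConfig`.
#' @export
spont_config <- function(frame_rate = 10, duration_s = 300,
                         fov = c(48L, 64L), hemi_semiaxes = c(18, 12),
                         hemi_col_center = 16,
                         event_rate = 6, coupling = 0.5,
                         mirror_time_jitter = 1, mirror_pos_jitter = 0.02,
                         band_sd = 0.15, p_split = 0.33,
                         amp_meanlog = log(0.12), amp_sdlog = 0.4,
                         tau_cal_s = 1.5, rise_frames = 1L,
                         baseline = 100, outside_baseline = 50,
                         noise_sd = 1,
                         bleach_tau_s = NULL,
                         motion_sd = 0, background_amp = 0,
                         seed = 1L) {
  stopifnot(coupling >= 0, coupling <= 1, event_rate >= 0, band_sd > 0,
            tau_cal_s > 0, frame_rate > 0, duration_s > 0,
            p_split > 0, p_split < 1)
  fov <- as.integer(fov)
  if (fov[2L] %% 2L != 0L)
    stop("fov width must be even for mirror-symmetric hemisphere masks",
         call. = FALSE)
  if (hemi_col_center + hemi_semiaxes[2L] > fov[2L] / 2 ||
      hemi_semiaxes[1L] >= fov[1L] / 2)
    stop("fov too small for the requested hemisphere geometry", call. = FALSE)
  structure(as.list(environment()), class = "SyntheticSpontConfig")
}

# Mirror-symmetric elliptical hemisphere masks for a given config.
make_ic_masks <- function(cfg) {
  nr <- cfg$fov[1L]; nc <- cfg$fov[2L]
  mid <- (nc + 1) / 2                        # mirror axis (half-integer)
  cy <- (nr + 1) / 2
  cxl <- nc / 2 - cfg$hemi_col_center + 0.5  # left ellipse centre column
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  left <- ((rows - cy) / cfg$hemi_semiaxes[1L])^2 +
    ((cols - cxl) / cfg$hemi_semiaxes[2L])^2 <= 1
  left[, cols[1, ] > mid] <- FALSE
  right <- mirror_mask(left, mid)
  roi_mask_set(left = left, right = right)
}

# Tonotopic geometry of one hemisphere: ordered column range from medial
# (next to the midline) to lateral, and the mapping p in [0,1] -> column.
hemi_tonotopy <- function(mask, midline) {
  cols <- range(which(colSums(mask) > 0))
  if (mean(cols) < midline) {            # left hemisphere: medial = max col
    list(medial = cols[2L], lateral = cols[1L], extent = cols[2L] - cols[1L])
  } else {
    list(medial = cols[1L], lateral = cols[2L], extent = cols[2L] - cols[1L])
  }
}

tonotopic_col <- function(p, tono) tono$medial + p * (tono$lateral - tono$medial)

# Band positions (tonotopic coordinates) rendered by an event at coordinate p:
# single band medially, a reversal-symmetric pair laterally.
band_positions <- function(p, p_split) {
  if (p < p_split) p else c(p, p_split + 1 - p)
}

# Temporal kernel: linear rise over `rise` frames to 1, then exponential
# decay with time constant tau (frames). Truncated when below 1e-3.
calcium_kernel <- function(tau_frames, rise = 1L) {
  n <- max(2L, ceiling(tau_frames * 7))
  decay <- exp(-(0:(n - 1L)) / tau_frames)
  if (rise > 0) c(seq_len(rise) / (rise + 1), decay) else decay
}

# Render one band-shaped event into the movie array (in place via return).
# profile: rows x cols amplitude-1 spatial footprint restricted to `mask`.
band_profile <- function(mask, tono, p, band_sd_px, p_split) {
  nr <- nrow(mask); nc <- ncol(mask)
  cols <- seq_len(nc)
  prof_cols <- rep(0, nc)
  for (pp in band_positions(p, p_split)) {
    cc <- tonotopic_col(pp, tono)
    prof_cols <- pmax(prof_cols, exp(-(cols - cc)^2 / (2 * band_sd_px^2)))
  }
  out <- matrix(prof_cols, nr, nc, byrow = TRUE)
  out[!mask] <- 0
  out
}

#' Generate a synthetic spontaneous-activity movie
#'
#' Draws Poisson event streams for each hemisphere, mirrors each event into
#' the other hemisphere with probability `coupling`, renders each event as a
#' Gaussian band (homogeneous along the major axis, confined across the
#' tonotopic axis) convolved with a rise-and-decay calcium kernel on top of a
#' constant baseline, and finally adds the configured artifacts (global
#' background fluctuation, bleaching, rigid motion, i.i.d. noise).
#'
#' @param cfg a [spont_config()].
#' @return A list with elements `movie` ([movie_stack()]), `masks`
#'   ([roi_mask_set()]), and `truth` (a `GroundTruth` data frame: one row per
#'   event with hemisphere, frame, tonotopic coordinate `p`, amplitude and
#'   mirrored-partner id, plus attributes `shifts` and `bleach`).
#' @export
generate_spontaneous_movie <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticSpontConfig"))
  masks <- make_ic_masks(cfg)
  mid <- find_midline(masks)
  if (!masks_mirror_symmetric(masks, mid))
    stop("hemisphere masks are not mirror-symmetric", call. = FALSE)
  nfr <- as.integer(round(cfg$duration_s * cfg$frame_rate))
  nr <- cfg$fov[1L]; nc <- cfg$fov[2L]

  with_seed(cfg$seed, {
    ## -- event streams ----------------------------------------------------
    ev <- list()
    nid <- 0L
    for (hemi in c("L", "R")) {
      n_ev <- rpois(1L, cfg$event_rate * cfg$duration_s / 60)
      if (n_ev == 0L) next
      frames <- sort(sample.int(nfr, n_ev, replace = TRUE))
      ps <- runif(n_ev)
      amps <- rlnorm(n_ev, cfg$amp_meanlog, cfg$amp_sdlog)
      mirrored <- runif(n_ev) < cfg$coupling
      for (i in seq_len(n_ev)) {
        nid <- nid + 1L
        ev[[length(ev) + 1L]] <- data.frame(
          id = nid, hemisphere = hemi, frame = frames[i], p = ps[i],
          amplitude = amps[i], partner_id = NA_integer_)
        if (mirrored[i]) {
          nid <- nid + 1L
          dt <- if (cfg$mirror_time_jitter > 0)
            round(rnorm(1, 0, cfg$mirror_time_jitter)) else 0
          dt <- max(-cfg$mirror_time_jitter, min(cfg$mirror_time_jitter, dt))
          dp <- if (cfg$mirror_pos_jitter > 0)
            rnorm(1, 0, cfg$mirror_pos_jitter) else 0
          ev[[length(ev) + 1L]] <- data.frame(
            id = nid, hemisphere = if (hemi == "L") "R" else "L",
            frame = min(max(frames[i] + dt, 1L), nfr),
            p = min(max(ps[i] + dp, 0), 1),
            amplitude = amps[i], partner_id = nid - 1L)
          ev[[length(ev) - 1L]]$partner_id <- nid
        }
      }
    }
    truth <- if (length(ev)) do.call(rbind, ev) else
      data.frame(id = integer(), hemisphere = character(), frame = integer(),
                 p = numeric(), amplitude = numeric(), partner_id = integer())

    ## -- render -----------------------------------------------------------
    arr <- array(0, dim = c(nr, nc, nfr))
    kern <- calcium_kernel(cfg$tau_cal_s * cfg$frame_rate, cfg$rise_frames)
    tono <- list(L = hemi_tonotopy(masks$left, mid),
                 R = hemi_tonotopy(masks$right, mid))
    for (i in seq_len(nrow(truth))) {
      h <- truth$hemisphere[i]
      mask <- if (h == "L") masks$left else masks$right
      tn <- tono[[h]]
      prof <- band_profile(mask, tn, truth$p[i],
                           cfg$band_sd * tn$extent, cfg$p_split)
      t0 <- truth$frame[i]
      tt <- t0:min(nfr, t0 + length(kern) - 1L)
      kk <- kern[seq_along(tt)] * truth$amplitude[i]
      arr[, , tt] <- arr[, , tt] +
        outer(prof, kk)
    }

    ## -- baseline and artifacts -------------------------------------------
    base <- matrix(cfg$outside_baseline, nr, nc)
    base[in_roi_mask(masks)] <- cfg$baseline
    arr <- arr * as.vector(base) + as.vector(base)

    if (cfg$background_amp > 0) {
      # slow global fluctuation: smoothed white noise, additive everywhere
      raw <- rnorm(nfr)
      bg <- as.numeric(stats::filter(raw, rep(1 / 15, 15), sides = 2))
      bg[is.na(bg)] <- 0
      bg <- cfg$background_amp * bg / max(sd(bg), 1e-12)
      arr <- arr + rep(bg, each = nr * nc)
    }

    shifts <- NULL
    if (cfg$motion_sd > 0) {
      shifts <- cbind(dy = rnorm(nfr, 0, cfg$motion_sd),
                      dx = rnorm(nfr, 0, cfg$motion_sd))
    }
    bleach <- NULL
    if (!is.null(cfg$bleach_tau_s)) {
      bleach <- list(tau_s = cfg$bleach_tau_s)
    }
    movie <- movie_stack(arr, frame_rate = cfg$frame_rate)
    movie <- inject_artifacts(movie, bleach = bleach, shifts = shifts,
                              noise_sd = cfg$noise_sd, seed = NULL)
    attr(truth, "shifts") <- shifts
    attr(truth, "bleach") <- bleach
    class(truth) <- c("GroundTruth", class(truth))
    list(movie = movie, masks = masks, truth = truth)
  })
}

#' Add bleaching, rigid motion and noise artifacts to a movie
#'
#' The inverse problems of these artifacts are what the preprocessing chain
#' solves, so they are injected with exactly known parameters. Bleaching
#' multiplies frame `t` (0-based) by the trend `exp(-t / tau)`; shifts
#' are applied as rigid bilinear translations with edge-replicated fill;
#' noise is i.i.d. additive Gaussian.
#'
#' @param movie a [movie_stack()].
#' @param bleach `NULL` or `list(tau_s =)`.
#' @param shifts `NULL` or an `n_frames x 2` matrix of `(dy, dx)` px.
#' @param noise_sd additive noise SD, a.u.
#' @param seed RNG seed for the noise; `NULL` uses the current RNG stream.
#' @return The corrupted `MovieStack`.
#' @export
inject_artifacts <- function(movie, bleach = NULL, shifts = NULL,
                             noise_sd = 0, seed = NULL) {
  stopifnot(inherits(movie, "MovieStack"))
  arr <- movie$data
  d <- dim(arr)
  if (!is.null(shifts)) {
    stopifnot(nrow(shifts) == d[3L], all(is.finite(shifts)))
    if (max(abs(shifts)) > min(d[1:2]) / 4)
      stop("shift magnitude exceeds field-of-view margin", call. = FALSE)
    for (t in seq_len(d[3L])) {
      if (any(shifts[t, ] != 0))
        arr[, , t] <- shift_frame(arr[, , t], shifts[t, 1L], shifts[t, 2L])
    }
  }
  if (!is.null(bleach)) {
    stopifnot(bleach$tau_s > 0)
    tau_f <- bleach$tau_s * movie$frame_rate
    fac <- exp(-(seq_len(d[3L]) - 1L) / tau_f)
    arr <- arr * rep(fac, each = d[1L] * d[2L])
  }
  add_noise <- function() {
    if (noise_sd > 0) arr + array(rnorm(length(arr), 0, noise_sd), dim = d)
    else arr
  }
  arr <- if (is.null(seed)) add_noise() else with_seed(seed, add_noise())
  movie$data <- arr
  movie
}

#' Default frequency tuning for synthetic evoked sessions
#'
#' Maps each protocol frequency to a tonotopic centre (log2-linear across the
#' tonotopic extent) and assigns a true auditory threshold per frequency.
#'
#' @param protocol a [build_stimulus_protocol()].
#' @param thresholds_db true thresholds, one per frequency (recycled).
#' @return Data frame with columns `frequency_khz`, `p_center`,
#'   `threshold_db`.
#' @export
evoked_tuning <- function(protocol, thresholds_db = 40) {
  f <- protocol$frequencies_khz
  data.frame(frequency_khz = f,
             p_center = (log2(f) - log2(min(f))) /
               max(log2(max(f)) - log2(min(f)), 1),
             threshold_db = rep_len(thresholds_db, length(f)))
}

#' Generate one synthetic tone-evoked imaging session
#'
#' Renders a session movie following a stimulus protocol: each trial spans
#' the protocol's per-trial frame count; during a trial, an evoked band is
#' placed at the stimulus frequency's tonotopic centre in both hemispheres.
#' Peak response amplitude is a saturating logistic function of SPL
#' calibrated to cross 2\% dF/F0 exactly at the frequency's true threshold:
#' `amp(SPL) = amp_max / (1 + exp(-(SPL - S50)/slope))` with
#' `S50 = threshold + slope * log(amp_max/0.02 - 1)`. The response holds its
#' peak during the 0.5-s stimulus then decays with the calcium time constant.
#'
#' @param protocol a [build_stimulus_protocol()].
#' @param tuning per-frequency tuning table from [evoked_tuning()].
#' @param session session index (selects the protocol's per-session trial
#'   order).
#' @param cfg a [spont_config()] supplying geometry, baseline, band width,
#'   decay and noise (its duration and event fields are ignored).
#' @param amp_max saturating response amplitude, dF/F0.
#' @param slope_db logistic slope, dB.
#' @param seed RNG seed for this session's noise.
#' @return List with `movie` (a `MovieStack`), `log` (trial log data frame:
#'   `session`, `trial`, `frequency_khz`, `spl_db`, `start_frame`), and
#'   `masks`.
#' @export
generate_evoked_session <- function(protocol, tuning, session = 1L,
                                    cfg = spont_config(), amp_max = 0.10,
                                    slope_db = 4, seed = 1L) {
  stopifnot(inherits(protocol, "StimulusProtocol"))
  if (!setequal(tuning$frequency_khz, protocol$frequencies_khz))
    stop("tuning frequencies do not match protocol frequencies", call. = FALSE)
  masks <- make_ic_masks(cfg)
  mid <- find_midline(masks)
  nr <- cfg$fov[1L]; nc <- cfg$fov[2L]
  fpt <- protocol$frames_per_trial
  order_idx <- protocol$session_orders[[((session - 1L) %%
                                           length(protocol$session_orders)) + 1L]]
  ntr <- length(order_idx)
  nfr <- ntr * fpt
  arr <- array(0, dim = c(nr, nc, nfr))

  # response time course within a trial: zero through the pre-stimulus
  # frames, plateau during the stimulus, calcium decay afterwards
  pre_f <- round(protocol$pre_s * protocol$frame_rate)
  stim_f <- round(protocol$stim_s * protocol$frame_rate)
  tau_f <- cfg$tau_cal_s * protocol$frame_rate
  course <- c(rep(0, pre_f), rep(1, stim_f),
              exp(-(seq_len(fpt - pre_f - stim_f)) / tau_f))

  tono <- list(L = hemi_tonotopy(masks$left, mid),
               R = hemi_tonotopy(masks$right, mid))
  logrows <- vector("list", ntr)
  for (k in seq_len(ntr)) {
    combo <- protocol$combinations[order_idx[k], ]
    tune <- tuning[tuning$frequency_khz == combo$frequency_khz, ]
    if (amp_max == 0) {
      amp <- 0                           # null response model
    } else {
      if (amp_max <= 0.02)
        stop("amp_max must exceed the 2% criterion (or be 0 for a null ",
             "response model)", call. = FALSE)
      s50 <- tune$threshold_db + slope_db * log(amp_max / 0.02 - 1)
      amp <- amp_max * plogis((combo$spl_db - s50) / slope_db)
    }
    t0 <- (k - 1L) * fpt
    for (h in c("L", "R")) {
      mask <- if (h == "L") masks$left else masks$right
      tn <- tono[[h]]
      prof <- band_profile(mask, tn, tune$p_center,
                           cfg$band_sd * tn$extent, cfg$p_split)
      arr[, , t0 + seq_len(fpt)] <- arr[, , t0 + seq_len(fpt)] +
        outer(prof, amp * course)
    }
    logrows[[k]] <- data.frame(session = session, trial = k,
                               frequency_khz = combo$frequency_khz,
                               spl_db = combo$spl_db, start_frame = t0 + 1L)
  }
  base <- matrix(cfg$outside_baseline, nr, nc)
  base[in_roi_mask(masks)] <- cfg$baseline
  arr <- arr * as.vector(base) + as.vector(base)
  movie <- movie_stack(arr, frame_rate = protocol$frame_rate)
  movie <- inject_artifacts(movie, noise_sd = cfg$noise_sd, seed = seed)
  list(movie = movie, log = do.call(rbind, logrows), masks = masks)
}
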