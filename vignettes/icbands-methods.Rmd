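---
title: "Models and methods behind icbands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind icbands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icbands)
```

`icbands` analyses wide-field calcium-imaging movies of the developing
inferior colliculus (IC): band-shaped spontaneous events, their bilateral
coupling, and tone-evoked responses. This vignette documents the models the
package implements, the tunable parameters and their defaults, the design
choices made where several reasonable options existed, and what the
synthetic-data tests do and do not establish about real recordings.

## The synthetic movie model

Real recordings of this preparation are not redistributable, so the package
ships a generator whose output has exactly known ground truth. Its model is
phenomenological, not biophysical:

* **Geometry.** Two mirror-symmetric elliptical hemisphere masks flank a
  vertical midline. The tonotopic axis runs horizontally in each
  hemisphere, from medial (`p = 0`, next to the midline) to lateral
  (`p = 1`). The default field of view is 48 × 64 px with semi-axes
  18 × 12 px — small enough that every test runs in seconds, large enough
  that bands, maps and embeddings are resolved.
* **Events.** Each hemisphere draws a Poisson stream (`event_rate`,
  default 6 events/min, a typical mid-prehearing value). An event has a
  tonotopic coordinate `p ~ U(0, 1)` and a lognormal peak amplitude
  (`meanlog = log(0.12)`, `sdlog = 0.4`), placing typical peaks at 5–30%
  ΔF/F0, i.e. above the 5% detection threshold with the geometric mean at
  ~12%. Its footprint is homogeneous along the band major axis and Gaussian
  across the tonotopic axis with SD `band_sd` (default 0.15 of the
  tonotopic extent). Events at `p < p_split` (default 0.33) render one
  band; lateral events render a pair of bands at reversal-symmetric
  positions, emulating the dorsal-surface tonotopic reversal (single band
  medially, dual bands laterally).
* **Kinetics.** A linear one-frame rise followed by exponential decay with
  `tau_cal` = 1.5 s at 10 Hz — a GCaMP6s-like response whose half-decay
  time sits in the one-to-several-seconds range.
* **Coupling.** With probability `coupling` an event is mirrored at the
  homologous tonotopic position of the other hemisphere with the same
  amplitude, a frame jitter bounded by `mirror_time_jitter` (default
  1 frame) and a tonotopic jitter `mirror_pos_jitter` (default 0.02).
  Coupling is a single probability — a deliberate abstraction of the
  brainstem efferent mechanism that mediates bilateral correlation in vivo.
  The generator makes no attempt to model its biology; it only provides a
  dial against which the correlation statistics must be monotone.
* **Artifacts.** Optional multiplicative photobleaching
  (`exp(-t / tau_b)`), per-frame rigid shifts (bilinear, edge-replicated),
  i.i.d. Gaussian noise (default SD 1 a.u. on a 100 a.u. baseline, i.e. 1%
  of baseline per pixel per frame), and a slow global background
  fluctuation added everywhere *including outside the ROI* — this last
  term exists specifically to exercise the partial-correlation control.

What passing tests on this generator show: the pipeline recovers known
rates, widths, shifts, decay constants, thresholds and coupling ordering
under realistic noise. What they do not show: robustness to non-rigid
motion, hemodynamic contamination, slow oscillations, uneven illumination,
or amplitude/width distributions of any particular age group — the paper
quantifies those per age, and the generator's defaults are a single
representative condition, not a calibration.

## Preprocessing decisions

* **Bleach fit.** A two-parameter single-term exponential fit by log-linear
  least squares on the frame-mean trace; the correction divides each frame
  by `f(t)/f(0)` (multiplicative, frame-0 scale preserved). Whether the
  original analysis corrected subtractively or divisively is not stated;
  divisive is chosen because bleaching is a multiplicative gain process.
  Non-decaying traces leave the movie unchanged with a flagged fit.
* **Registration.** Fourier cross-correlation against the session mean
  frame with two-stage 10× upsampled local DFT refinement (0.01 px grid).
  The cross power is deliberately *not* whitened: classic phase
  correlation equalizes all frequencies, and on smooth widefield images
  most of the spectrum is empty, so whitening amplifies noise phases and —
  against a blurred mean reference — biased shifts by more than a pixel in
  development testing. The integer search is bounded to ±5 px: the
  bilateral field contains two near-identical hemisphere patterns one
  hemisphere spacing apart, and an unbounded search can lock onto that
  self-similarity alias, while genuine rigid brain motion is far smaller
  (frames above 0.5 px are flagged corrupted and excluded downstream).
* **Smoothing.** "σ/filter size = 1" is read as a Gaussian with σ = 1 px,
  truncated at 4σ, with replicate boundary handling (implemented by
  edge-padding before convolution so the kernel never exceeds small test
  frames).
* **Pooling.** 2×2 average pooling; blocks straddling the ROI use in-mask
  members only; odd trailing rows/columns are dropped with a warning.
* **SVD denoising.** The movie's pixels-by-frames matrix is reconstructed
  from leading singular components. The original rank is unspecified; the
  default keeps the first component (the static baseline pattern, which
  dominates raw energy) plus enough further components to explain 90% of
  the remaining fluctuation energy, and `k` is directly overridable.
  Applying the energy rule to the raw spectrum would stop at rank 1 and
  delete the signal — hence the split rule.
* **F0.** Per-pixel 5th percentile with linear interpolation between order
  statistics (the most common percentile convention, declared so the
  sorting-oracle test is exact).
* **Control trace.** The outside-ROI mean trace used as the
  partial-correlation control is captured from the registered movie
  *before* smoothing: smoothing leaks hemisphere activity into background
  pixels that border the ROI, and a contaminated control regresses out
  genuine bilateral signal rather than non-specific fluctuations.

## Event detection decisions

Line-scan maps average the movie along the band major axis inside a
rectangle; the angle can be supplied or estimated from image moments of the
thresholded mean-activity image (always logged and overridable — the
original analysis drew these interactively). Peaks are joint 1-D maxima
along the spatial and temporal directions of the 5×5 boxcar-smoothed map
("spatiotemporal filter" is read as a mean filter, declared for
reproducibility), at or above 5% ΔF/F0; plateau ties resolve to the first
index.

Widths are full widths at half maximum on the smoothed map. Two measurement
details matter:

* The half level is referenced to the map's event-free baseline (its
  median), not to absolute zero. Percentile-based F0 normalization under
  noise leaves a small positive pedestal (≈ +1.6% ΔF/F0 at default noise),
  and a zero-referenced half level would widen every event by 10–15%.
* The half-crossing walk stops at a genuine valley (a local minimum below
  80% of the peak's prominence), so a merged neighboring event cannot
  extend the measured width; events clipped by the record edge keep twice
  the measurable side and carry an `edge` flag.

When recovered bandwidths are compared with the generator's, the known
variance contribution of the 5×5 boxcar, `(k² − 1)/12` bins², is subtracted
first — instrument-response deconvolution, since the measurement is defined
on the smoothed map. Rate- and width-recovery experiments run the generator
in its single-band regime (`p_split` near 1), because the Poisson and
Gaussian-FWHM oracles apply per event only when each event renders exactly
one band; the dual-band reversal geometry is exercised by the correlation
and seed-selection tests instead. Events whose temporal FWHM interval
overlaps any motion-corrupted frame are censored from all summaries; the
censoring granularity is a single frame, the smallest unit the motion trace
resolves.

## Correlation analysis decisions

All bilateral statistics are first-order partial correlations controlling
one regressor, the outside-ROI mean (exactly one control; multi-regressor
control is intentionally not implemented). A constant control falls back to
plain Pearson with a message; a collinear control is an explicit error.
The midline is detected as the vertical axis maximizing the overlap of the
combined hemisphere masks with their reflection — this replaces the
interactive drawing of symmetric contralateral regions. Neighborhood means
at ROI borders use in-region members only; ties in the maximum search break
to the smallest row, then column.

Representative low/mid/high seeds walk the seed-grid lane nearest the left
hemisphere's centre row from medial to lateral: the low seed is the most
medial with a single suprathreshold band, the mid and high seeds lie three
grid steps further lateral at the first dual-band positions. The
suprathreshold level defining a "visible" band (0.6) is not given by the
source analysis and is exposed in configuration; band counting is by runs
of active columns in the thresholded ipsilateral map. Slots without a
qualifying seed report "not found" rather than guessing, and the averaged
SbBC is only defined when all three exist.

Region morphology thresholds the map at r > 0.95, takes the connected
component containing the seed, and fits an ellipse by second central
moments (with the standard 1/12 per-pixel term); eccentricity is the axis
ratio a/b and the proportion is the component area over the hemisphere
area.

## Diffusion map decisions

The affinity is `exp(−d²/σ²)` — no factor of 2 in the denominator, a
convention that must be fixed for the stated σ rule
(σ = 2·SD of all pairwise distances) to be meaningful. Eigenpairs come from
the symmetric conjugate of the row-normalized Markov matrix, so eigenvalues
are real and the solver is deterministic; each eigenvector's sign is fixed
by its largest-magnitude entry. Diffusion time t = 1 by default, exposed.
The dense solver is intentional: after 2×2 pooling a field has well under
3000 in-ROI pixels, and the guard refuses larger problems rather than
silently switching algorithms.

## Evoked analysis decisions

The protocol is fixed arithmetic: 7 half-octave frequencies (4–32 kHz) ×
12 levels (96→8 dB SPL in 8-dB steps) = 84 combinations; 5-s trials
(1 s pre, 0.5 s stimulus, 3.5 s post) give exactly 50 frames at 10 Hz and
4200-frame sessions; per-session order is a seeded permutation. Frame
windows are quoted 1-based inclusive ("frames 11–15" is `11:15` in R), and
the package keeps R's native 1-based indexing throughout so the quoted
windows are literal.

Session movies are preprocessed (all steps except ΔF/F0), trials averaged
per condition across sessions, and the average normalized against the mean
of its first 10 frames. Pooling uses plain Pearson correlation on the
averaged entry — at the 0.997 level the pooled pixels are near-duplicates
of the max-responding pixel, and no control regressor is involved in this
step. The threshold rule is literal: responding means the pooled curve
reaches 2% ΔF/F0 anywhere in frames 11–20 (single-sample crossing; whether
a sustained crossing was required is unstated, so the weakest reading is
used), and the threshold is the lowest responding SPL even when the
responding pattern is non-monotone (a warning is logged). The synthetic
evoked model drives response amplitude through a logistic function of SPL
calibrated to cross 2% exactly at the configured true threshold
(`amp_max = 0.10`, slope 4 dB); the measurement chain attenuates band peaks
by ~15–20% (smoothing + pooling), so recovered thresholds sit at or one
8-dB step above truth — within the step tolerance the discrete level
ladder imposes anyway.

## Problem sizes

Tests and the acceptance script use a 48 × 64 px (or smaller) field.
Rate/bandwidth recovery uses one 30-minute movie at 6 events/min;
threshold recovery uses 10 noise replicates of 6 single-frequency sessions;
coupling monotonicity uses 5 replicates × 3 coupling levels of 4-minute
movies. These sizes give the oracles comfortable statistical room (3·SE
bands on Poisson counts, ±1 level on thresholds) while the whole suite
runs in a few minutes on one CPU.

## Known limitations

* Rigid translation only; no non-rigid registration.
* One control regressor; no hemodynamic or crosstalk correction.
* The generator's band geometry is separable (Gaussian × homogeneous) and
  its reversal is an idealized mirror; real dual bands tilt and curve.
* Representative-seed selection assumes the left hemisphere and a
  roughly horizontal tonotopic axis after preprocessing.
* Group-level statistics across animals are out of scope; the package
  stops at per-recording summaries.
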