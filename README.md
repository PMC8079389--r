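# icbands

Analysis of bilateral spontaneous and tone-evoked activity in wide-field
calcium-imaging movies of the developing auditory midbrain (inferior
colliculus, IC).

Before hearing onset, the IC shows discrete, band-shaped spontaneous calcium
events: elongated along the major axis of each hemisphere and confined along
the future tonotopic axis, appearing as a single band medially and as dual
bands more laterally (the tonotopic reversal of the IC dorsal surface).
Corresponding bands often occur near-simultaneously at homologous tonotopic
positions of the two hemispheres. `icbands` implements the complete analysis
chain for such recordings, plus a seeded synthetic-movie generator with known
ground truth so that every stage can be verified without raw recordings.

## What the package computes

* **Preprocessing** (`preprocess_movie`): photobleach correction by a
  single-term exponential fit `f(t) = A e^{-t/τ}` to the frame-mean trace
  (divisive), subpixel rigid registration by Fourier cross-correlation with
  upsampled local refinement (frames with shift amplitude > 0.5 px flagged
  motion-corrupted), Gaussian smoothing (σ = 1 px), ROI masking and 2×2
  average pooling, SVD denoising, and ΔF/F0 normalization with per-pixel F0
  at the 5th percentile.
* **Band events** (`compute_line_scan`, `detect_band_peaks`,
  `summarize_events`): movies are reduced to line-scan maps (tonotopic
  position × time) by averaging along the band major axis; spatiotemporal
  peaks are joint 1-D maxima along both directions of the 5×5-smoothed map
  above a 5% ΔF/F0 threshold. Five statistics: event frequency (/min),
  duration (temporal FWHM, s), inter-peak interval (s, same-frame peaks
  collapsed), normalized bandwidth (spatial FWHM / IC width), and peak
  amplitude (ΔF/F0).
* **Bilateral correlations** (`global_bilateral_correlation`,
  `seed_correlation_map`, `bilateral_stats`): first-order partial
  correlations controlling for the mean fluorescence trace over all pixels
  outside the ROI,
  `r_xy·z = (r_xy − r_xz r_yz) / √((1−r_xz²)(1−r_yz²))`.
  Seed-based maps over a 1000-seed lattice; the seed-based bilateral
  correlation (SbBC) is the best 5×5 neighborhood-mean correlation inside
  the mirror-symmetric contralateral region; high-correlation regions are
  reduced to ellipse aspect ratio and area fraction.
* **Diffusion embedding** (`diffusion_map`): pixels are embedded in 3-D by
  eigenfunctions of the Markov matrix of a Gaussian-affinity graph,
  `W_ij = exp(−d_ij²/σ²)` with σ = 2·SD of all pairwise trace distances.
* **Evoked thresholds** (`build_stimulus_protocol`, `run_evoked_pipeline`):
  SAM tones 4–32 kHz in half-octave steps × 96→8 dB SPL in 8-dB decrements
  (84 combinations; 50 frames/trial at 10 Hz; 4200-frame sessions), trial
  averaging per condition across sessions, ΔF/F0 against the first 10
  frames, response pooling over the r > 0.997 region around the
  max-responding pixel (frames 11–15), and the auditory threshold as the
  lowest SPL whose pooled curve crosses 2% ΔF/F0 during frames 11–20.
* **Synthetic data** (`spont_config`, `generate_spontaneous_movie`,
  `generate_evoked_session`, `inject_artifacts`): Poisson band events with
  lognormal amplitudes, GCaMP6s-like rise-and-decay kernels, a tunable
  probability `coupling` that an event is mirrored contralaterally,
  tonotopic reversal (dual bands lateral of `p_split`), and optional
  bleaching, rigid motion, global background fluctuation and noise — each
  with exactly known ground truth.

## Worked example

```r
library(icbands)

cfg <- spont_config(duration_s = 300, coupling = 0.8, event_rate = 8,
                    seed = 42)
sim <- generate_spontaneous_movie(cfg)
res <- run_spontaneous_pipeline(analysis_config(), sim$movie, sim$masks)

res$summary[, 1:5]
#>  frequency_per_min mean_duration_s mean_ipi_s norm_bandwidth mean_amplitude
#>                 10            1.47       5.82          0.658          0.114
res$bilateral
#> <BilateralStats> global r = 0.8893 | SbBC low 0.8713 mid 0.8568 high NA | avg NA
res$embedding
#> <DiffusionEmbedding> 376 pixels, t = 1, lambda_2..4 = 0.6658, 0.2538, 0.1843
```

The generator planted 8 band events per minute per hemisphere, 80% of them
mirrored contralaterally: the detector recovers 10 bands/min (dual-band
events laterally of the reversal contribute two bands each), events last
~1.5 s, and the global bilateral partial correlation is 0.89. The `high`
SbBC slot is `NA` because no qualifying dual-band seed was found three grid
steps lateral of the mid seed in this short record; the averaged SbBC is
reported only when all three representative seeds exist.

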