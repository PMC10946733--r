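---
title: "Methods: onset-locked ERSP analysis of active touch with single-trial sensor fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: onset-locked ERSP analysis of active touch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis problem

When a person actively strokes a textured surface, sensorimotor cortex
shows event-related desynchronisation (ERD): a drop of narrowband
alpha (8–12 Hz) and beta (16–24 Hz) power relative to a pre-movement
baseline. Quantifying how ERD depends on the texture being explored
and on the perceptual task (estimating sensory versus hedonic surface
properties, or no estimation) requires disentangling genuinely central
effects from the peripheral consequences of touch behaviour itself:
people press harder and experience more friction on rough surfaces, so
friction and load must be measured trial-by-trial and entered into the
statistical model as covariates.

`atersp` implements that full chain:

1. **Touch kinetics.** A six-axis force/torque sensor under the
   texture records `Fx, Fy, Fz, Mx, My, Mz` at the sensor rate. After
   block-averaging to 20 Hz, the contact point is the centre of
   pressure under static equilibrium, `x = (-My - Fx*h)/Fz`,
   `y = (Mx - Fy*h)/Fz` (plate thickness `h`, default 3 mm); friction
   is the tangential magnitude `sqrt(Fx^2 + Fy^2)`; load is `|Fz|` in
   grams-force (standard gravity 9.80665).
2. **Movement onset.** Signed per-axis velocities are obtained by
   first differences in a −200…4000 ms window around the go cue; the
   onset is the earliest first local maximum of `v` (or of `-v`) with
   height at least half the extremum, prominence 1 trace unit and
   minimum separation 1 sample.
3. **Trial QC.** Trials are rejected for a missing trigger, movement
   during the baseline/cue period (speed above 5 mm/s by default),
   onset later than 400 ms after the cue (strict), and — within each
   subject × block × texture group — any median covariate whose
   |z| strictly exceeds 2 (sample SD, single pass).
4. **Onset-locked ERSP.** EEG (1–100 Hz band-pass, 50 ± 2 Hz notch,
   both zero-phase Butterworth) is epoched −5.5…5 s around each
   accepted trial's onset marker, downsampled, common-average
   referenced, screened for peak-to-peak artifacts, convolved with
   5-cycle complex Morlet wavelets (1–40 Hz), log-ratio
   baseline-normalised (`10*log10(P/mean P_baseline)`, baseline
   −4…−2 s), band-averaged on the dB scale, and cropped to 0–4 s.
5. **Scalp-time statistics.** Channel values are projected
   (azimuthal-equidistant) and linearly interpolated onto a 32 × 32
   grid (pixels 4.25 × 5.38 mm, extents −68…68 / −98…72 mm), stacked
   over time, smoothed with a 9 × 9 mm × 20 ms FWHM Gaussian
   (mask-weighted), and modelled per subject with a single-trial GLM:
   six cell dummies (texture × estimation) plus six mean-centred
   friction+load parametric regressors. Subject contrast images enter
   one-sample (texture) or joint two-contrast (estimation,
   interaction) second-level F tests; voxels above the p < .001
   uncorrected threshold form clusters under 18-connectivity and
   clusters below 35 voxels are discarded. Cluster power is extracted
   per subject and condition for post-hoc paired t / repeated-measures
   ANOVA.
6. **Behavioural statistics.** VAS ratings (2 textures × 4 blocks) and
   touch behaviour (2 × 3) are tested with within-subject ANOVAs;
   Greenhouse–Geisser correction is applied when Mauchly's test
   rejects sphericity; post-hoc comparisons are Bonferroni-adjusted;
   a correlation screen decides which touch covariates are combined by
   summation (friction and load, in practice) and which are excluded
   (speed, which differentiates neither texture nor task).

# The synthetic-data generator

Every stage is validated against a generator whose ground truth is
known exactly.

**Touch.** A trial is stationary through the 4-s baseline and 1-s
indicator period, then performs 1-D oscillatory strokes (2.5 Hz,
random direction, peak speed ≈ 150 mm/s) from a drawn onset latency.
The tangential force opposes the velocity with magnitude
`mu * |Fz|` — hessian `mu = 0.9`, silk `mu = 0.45`, with 12%
trial-to-trial jitter — so friction and load are strongly correlated
across trials, as Amontons' law dictates. Moments encode the contact
point through the same static-equilibrium expressions the kinetics
module inverts, making centre-of-pressure recovery exact when noise is
switched off. Loads are drawn per trial (150 ± 30 g, subject SD 20 g,
small estimation-condition shifts) so the behavioural ANOVAs have
realistic effects to find.

**Onset convention.** The generator defines the ground-truth onset as
the time of the *first velocity peak* of the initial stroke — the
event the peak-picking detector estimates and the event to which EEG
effects are locked. The detector, which works on 20-Hz block-averaged
kinetics, carries a ≈ +25 ms sampling bias, so latencies are drawn
truncated to 150–390 ms; deliberately "late" trials are drawn at
500–700 ms. Configurable fractions of trials violate each QC rule and
are flagged in the ground-truth table, so rejection tests are exact
set comparisons, not statistical ones.

**EEG.** Channels carry pink (1/f) background noise (Kellet-filter
realisation; 18 dB re 1 µV RMS) plus alpha and beta oscillators on
geometrically defined channel groups (e.g. left sensorimotor for
right-hand exploration). From onset to the end of exploration the
oscillator amplitude is scaled by `10^(erd_db/20)` with a 150-ms
raised-cosine ramp, so the pipeline's own log-ratio ERSP recovers
`erd_db` — within 0.1 dB in the noiseless case. Default injected
effects follow the texture and estimation structure the analysis is
designed to detect: alpha ERD of −3.36 dB (hessian) versus −1.91 dB
(silk) over contralateral sensorimotor cortex; sensory −1.87,
no-estimation −1.23, hedonic −0.16 dB over ipsilateral posterior
parietal cortex; beta −2 dB texture-independent. Between-subject ERD
variability is not characterised in the source literature; it is
exposed as a configuration SD with a default of 0.35 dB, a modest
value chosen once so that desk-scale group analyses are adequately
powered.

**What the generator does not emulate.** Ocular, cardiac and muscle
artifacts (a peak-to-peak amplitude screen stands in for manual
inspection and component-based removal); volume conduction through a
head model (oscillators are injected directly into channels, with
random phase per channel and trial); slip–stick micro-events; and
non-stationary background spectra. Passing tests therefore demonstrate
that the analysis machinery is correct and adequately powered for
effects of the stated size and geometry — not that it is robust to
every artifact class found in real recordings.

# Design choices where the method was genuinely open

* **Centre of pressure.** The standard force-plate inversion with an
  optional plate-thickness term; generator and kinetics share the
  convention (compression gives `Fz < 0`), making the pair
  self-consistent and the recovery testable to machine precision.
* **Onset velocities.** Per-axis signed velocity is the default
  (extrema of nonnegative scalar speed are not meaningful for the
  min/max rule); a scalar-speed mode is available. Peak "prominence
  and distance of 1" are interpreted as 1 trace unit and 1 sample —
  the permissive defaults of common peak pickers.
* **Filters and resampling.** Zero-phase 4th-order Butterworth
  (phase distortion would bias latency claims); downsampling is
  Fourier spectrum-truncation, an ideal anti-alias low-pass for the
  retained band. Both are recorded in provenance metadata.
* **ERSP conventions.** Wavelets are unit-energy (the log-ratio makes
  results invariant to this); convolution uses reflective padding and
  a per-frequency edge-validity margin of 3 sigma_t; baseline
  statistics use the arithmetic mean of power over −4…−2 s; band
  averaging happens *after* dB conversion (a discriminating unit test
  pins this order); `10*log10` is the default scale with a
  natural-log mode available.
* **Scalp geometry.** Azimuthal-equidistant projection (stereographic
  would compress the vertex less, but equidistant is the common EEG
  flattening); pixels outside the electrode convex hull are masked
  rather than extrapolated, and smoothing is mask-weighted so border
  voxels are not attenuated. The Delaunay triangulation behind the
  linear interpolation is implemented in the package (Bowyer–Watson);
  its empty-circumcircle property is verified in the test suite.
* **Covariate centring.** The parametric regressors are centred by
  the grand mean of the friction+load modulator before being placed
  in their cell columns. Of the three implemented policies (grand,
  whole-column, per-cell), only grand-mean centring makes dummy
  contrasts invariant to the modulator's origin while keeping each
  covariate column confined to its cell; per-cell centring
  deliberately reproduces unadjusted cell means. The raw
  friction+load summation mixes newtons with grams-force; a
  z-standardised summation (`covariate_mode = "zsum"`) is provided
  and recommended when the covariate must absorb confounds expressed
  in standardised units.
* **Cluster inference.** The decision rule is exactly "p < .001
  uncorrected + extent ≥ 35 voxels" under 18-connectivity (6 and 26
  available). No random-field or permutation correction is applied —
  the empirical null behaviour of the rule is characterised instead
  (below). Peak ties break toward earlier latency, then lower y, then
  lower x.
* **Sphericity.** Greenhouse–Geisser epsilon is reported for every
  effect and applied when Mauchly's test (implemented) rejects at
  .05, with "always"/"never" modes; a non-computable Mauchly test
  (too few subjects) is treated conservatively as a violation.

# Problem sizes and power

The default desk-scale study is 8 subjects × 12 trials per
texture × condition cell on a 32-channel montage — large enough that
the injected −3.36 versus −1.91 dB texture difference is detected as a
significant sensorimotor cluster in essentially every seeded
replicate, yet small enough to re-run routinely. The validation suite
runs this study at a 128-Hz EEG rate with alpha-band wavelets only and
16-Hz scalp-time frames; the empirical null calibration uses an even
smaller layout (2 trials/cell, 16 channels, 64 Hz, 8-Hz frames, zero
injected effects) across 100 seeded replicates, where the observed
any-cluster rate is far below the 0.20 bound we require of the
uncorrected-threshold + extent heuristic. A full-scale configuration
(31 subjects × 60 trials/cell, 128 channels, 1000 Hz) is provided by
`paper_scale_config()` for completeness.

Numerical tolerances used by the validation suite: FFT versus direct
convolution agree to a relative 1e−9; OLS, contrast, extraction and
ANOVA computations agree with brute-force oracles to 1e−9…1e−12;
noiseless dB recovery is exact to 0.05–0.1 dB; onset recovery is
within ±50 ms on ≥ 95% of valid trials (one 20-Hz kinetics sample on
either side of the true velocity peak).

# Known limitations

* The amplitude-rejection artifact screen does not emulate
  component-based ocular/cardiac removal; analyses of real recordings
  should substitute their own artifact pipeline before
  `epoch_to_onsets()`.
* Channel-injected oscillators ignore volume conduction, so the
  spatial spread of simulated effects is narrower than in real EEG;
  cluster extents on real data will differ.
* The EEG fixture format is a plain channel-by-sample TSV; EDF/EDF+
  readers are not bundled.
* First-level designs with very few trials per cell (fewer than two)
  are rank-deficient by construction and are refused rather than
  regularised.
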