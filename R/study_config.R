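#' Default injected ERD/ERS effect table
#'
#' One row per (texture, condition, band, channel group) combination that
#' receives a band-limited power change after movement onset, in dB
#' relative to the pre-onset oscillation amplitude (negative values are
#' event-related desynchronisation). The defaults encode the effect
#' structure the analysis is designed to detect: a texture effect on
#' contralateral (left, for right-hand exploration) sensorimotor alpha
#' (hessian -3.36 dB vs silk -1.91 dB), a condition effect on ipsilateral
#' posterior-parietal alpha (sensory -1.87, no-estimation -1.23, hedonic
#' -0.16 dB), and a texture-independent beta ERD of -2 dB over
#' sensorimotor cortex.
#'
#' @return data.frame with columns `texture`, `condition`, `band`,
#'   `group`, `erd_db`. `texture`/`condition` may be `"*"` meaning
#'   "applies to every level".
#' @export
default_erd_table <- function() {
  rbind(
    data.frame(texture = "hessian", condition = "*", band = "alpha",
               group = "sensorimotor_left", erd_db = -3.36),
    data.frame(texture = "silk", condition = "*", band = "alpha",
               group = "sensorimotor_left", erd_db = -1.91),
    data.frame(texture = "*", condition = "sensory", band = "alpha",
               group = "parietal_right", erd_db = -1.87),
    data.frame(texture = "*", condition = "hedonic", band = "alpha",
               group = "parietal_right", erd_db = -0.16),
    data.frame(texture = "*", condition = "none", band = "alpha",
               group = "parietal_right", erd_db = -1.23),
    data.frame(texture = "*", condition = "*", band = "beta",
               group = "sensorimotor_left", erd_db = -2.0)
  )
}

TEXTURES <- c("hessian", "silk")
CONDITIONS <- c("sensory", "hedonic", "none")

#' Study configuration for the synthetic generator
#'
#' Bundles every parameter of the simulated experiment: trial structure,
#' sampling rates, touch mechanics (friction coefficients, load), onset
#' latencies, injected EEG effects and noise. The default is a
#' "desk-scale" study (8 subjects, 12 trials per texture x condition
#' cell, 32 channels) small enough for routine re-analysis;
#' [paper_scale_config()] returns the full-scale layout (31 subjects,
#' 60 trials per cell, 128 channels).
#'
#' @param n_subjects number of subjects
#' @param trials_per_cell trials per texture x condition cell (>= 1)
#' @param n_blocks experimental blocks; trials of each cell are spread
#'   round-robin across blocks so every subject x block x texture cell
#'   is populated
#' @param fs_sensor,fs_eeg sampling rates, Hz
#' @param baseline_s,cue_s,explore_s,iti_s durations of the baseline
#'   fixation, condition-indicator, exploration and inter-trial
#'   intervals, seconds
#' @param n_channels EEG channel count (montage size)
#' @param mu_friction named numeric, kinetic friction coefficient per
#'   texture (rough hessian > smooth silk)
#' @param mu_trial_cv per-trial coefficient of variation of the friction
#'   coefficient (lognormal-free multiplicative jitter)
#' @param load_mean_g,load_sd_g per-trial finger load draw, grams-force
#' @param load_subject_sd_g between-subject SD of mean load, grams-force
#' @param load_condition_shift_g named numeric, additive load shift per
#'   estimation condition, grams-force
#' @param speed_mean_mms,speed_sd_mms,speed_subject_sd_mms peak stroke
#'   speed draw, mm/s
#' @param stroke_hz frequency of exploratory strokes, Hz; the first
#'   velocity peak (the ground-truth movement onset) occurs a quarter
#'   stroke period after motion begins
#' @param onset_latency_mean_ms,onset_latency_sd_ms latency of the first
#'   velocity peak after the go cue; draws are truncated to
#'   `[150, 390]` ms so valid trials always satisfy the 400-ms rule
#' @param erd_db injected effect table, see [default_erd_table()]
#' @param erd_subject_sd_db between-subject SD added independently to
#'   every (texture, band, group) effect, dB
#' @param alpha_hz,beta_hz oscillation centre frequencies, Hz
#' @param alpha_amp_uV,beta_amp_uV pre-onset oscillation amplitudes
#' @param noise_db broadband 1/f background level, dB re 1 uV RMS
#' @param sensor_noise_frac multiplicative noise fraction on tangential
#'   force (0 gives exact friction = mu * load coupling)
#' @param confound_db_per_unit coupling between the standardised
#'   friction+load sum of a trial and the post-onset oscillation power
#'   (dB per SD unit); 0 by default, used in covariate-recovery studies
#' @param violation_rate fraction of trials that deliberately violate a
#'   QC rule (late onset, baseline movement, missing trigger); flagged
#'   in the ground truth
#' @param violation_types which violation kinds are injected (cycled in
#'   order over the flagged trials); `"zscore_outlier"` (an extreme
#'   load) may be added for quality-control exactness studies
#' @param plate_h_m force-plate surface-to-sensor-origin thickness, m
#' @param ratings_mean VAS rating means per scale and texture (named
#'   list of 2-vectors c(hessian, silk))
#' @param ratings_sd,ratings_subject_sd trial and subject rating SDs
#' @param ratings_block_drift per-block additive drift applied to
#'   hedonic ratings of hessian (habituation-like decline)
#' @param seed RNG seed fixing every draw
#' @return an object of class `study_config` (a validated list)
#' @export
study_config <- function(n_subjects = 8,
                         trials_per_cell = 12,
                         n_blocks = 4,
                         fs_sensor = 1000,
                         fs_eeg = 1000,
                         baseline_s = 4, cue_s = 1, explore_s = 4,
                         iti_s = 2,
                         n_channels = 32,
                         mu_friction = c(hessian = 0.9, silk = 0.45),
                         mu_trial_cv = 0.12,
                         load_mean_g = 150, load_sd_g = 30,
                         load_subject_sd_g = 20,
                         load_condition_shift_g = c(sensory = 0,
                                                    hedonic = 10,
                                                    none = -8),
                         speed_mean_mms = 150, speed_sd_mms = 20,
                         speed_subject_sd_mms = 15,
                         stroke_hz = 2.5,
                         onset_latency_mean_ms = 250,
                         onset_latency_sd_ms = 60,
                         erd_db = default_erd_table(),
                         erd_subject_sd_db = 0.35,
                         alpha_hz = 10, beta_hz = 20,
                         alpha_amp_uV = 20, beta_amp_uV = 10,
                         noise_db = 18,
                         sensor_noise_frac = 0.05,
                         confound_db_per_unit = 0,
                         violation_rate = 0.05,
                         violation_types = c("late_onset",
                                             "baseline_movement",
                                             "no_trigger"),
                         plate_h_m = 0.003,
                         ratings_mean = list(
                           pleasant = c(hessian = 38, silk = 72),
                           comfort  = c(hessian = 40, silk = 70),
                           smooth   = c(hessian = 25, silk = 78),
                           soft     = c(hessian = 30, silk = 74)),
                         ratings_sd = 12,
                         ratings_subject_sd = 8,
                         ratings_block_drift = -2.5,
                         seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "study_config"
  validate_study_config(cfg)
  cfg
}

#' Full-scale study layout
#'
#' The configuration matching the original experiment's dimensions:
#' 31 subjects, 60 trials per texture x condition cell (360 per subject),
#' 128 recording channels sampled at 1000 Hz. Too large for routine
#' testing; provided for completeness.
#'
#' @param ... overrides passed on to [study_config()]
#' @return a `study_config`
#' @export
paper_scale_config <- function(...) {
  study_config(n_subjects = 31, trials_per_cell = 60, n_channels = 128,
               fs_eeg = 1000, ...)
}

validate_study_config <- function(cfg) {
  chk <- function(ok, msg, ...) if (!ok) stop_atersp("config", msg, ...)
  chk(cfg$trials_per_cell >= 1, "trials_per_cell must be >= 1")
  chk(cfg$n_subjects >= 1, "n_subjects must be >= 1")
  for (f in c("fs_sensor", "fs_eeg", "baseline_s", "cue_s", "explore_s",
              "iti_s", "stroke_hz"))
    chk(is.numeric(cfg[[f]]) && cfg[[f]] > 0, "%s must be > 0", f)
  chk(all(TEXTURES %in% names(cfg$mu_friction)),
      "mu_friction must name both textures")
  chk(all(cfg$mu_friction > 0), "friction coefficients must be > 0")
  chk(all(is.finite(cfg$erd_db$erd_db)), "erd_db values must be finite")
  chk(all(c("texture", "condition", "band", "group", "erd_db") %in%
          names(cfg$erd_db)), "erd_db table is missing columns")
  chk(cfg$violation_rate >= 0 && cfg$violation_rate < 1,
      "violation_rate must be in [0, 1)")
  chk(cfg$n_channels >= 2, "n_channels must be >= 2")
  chk(length(cfg$seed) == 1 && is.finite(cfg$seed),
      "seed must be a single finite number")
  invisible(cfg)
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic active-touch study configuration\n",
    "  %d subjects x %d trials/cell (%d trials/subject), %d blocks\n",
    "  sensor %g Hz, EEG %g Hz, %d channels\n",
    "  trial: %gs baseline + %gs cue + %gs exploration + %gs ITI\n",
    "  mu: hessian %.2f, silk %.2f; load %g +/- %g g\n",
    "  injected effects: %d rows; violation rate %.0f%%; seed %s\n"),
    x$n_subjects, x$trials_per_cell, x$trials_per_cell * 6, x$n_blocks,
    x$fs_sensor, x$fs_eeg, x$n_channels,
    x$baseline_s, x$cue_s, x$explore_s, x$iti_s,
    x$mu_friction[["hessian"]], x$mu_friction[["silk"]],
    x$load_mean_g, x$load_sd_g,
    nrow(x$erd_db), 100 * x$violation_rate, format(x$seed)))
  invisible(x)
}
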