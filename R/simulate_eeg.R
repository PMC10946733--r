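# Synthetic EEG: 1/f background plus narrowband oscillators whose
# post-onset amplitude encodes the injected ERD/ERS in dB.

# Pink (1/f) noise: white noise shaped by the Kellet IIR pinkening
# filter (-10 dB/decade power slope), scaled per channel to the target
# RMS. Time-domain filtering keeps slot-wise generation cheap.
PINK_B <- c(0.049922035, -0.095993537, 0.050612699, -0.004408786)
PINK_A <- c(1, -2.494956002, 2.017265875, -0.522189400)

one_over_f_noise <- function(n, nch, fs, rms_uV) {
  if (rms_uV <= 0) return(matrix(0, nch, n))
  burn <- 256
  w <- matrix(stats::rnorm((n + burn) * nch), n + burn, nch)
  ma <- stats::filter(w, PINK_B, method = "convolution", sides = 1)
  ma[is.na(ma)] <- 0
  x <- stats::filter(ma, -PINK_A[-1], method = "recursive")
  x <- matrix(x[burn + seq_len(n), ], n, nch)
  sds <- sqrt(pmax(colMeans(x^2) - colMeans(x)^2, 1e-300))
  t(x) * (rms_uV / rep(sds, each = 1))      # channels x samples
}

#' Effective injected effects for one trial
#'
#' Resolves the configured effect table for a given texture and
#' estimation condition: wildcard rows (`"*"`) are expanded, multiple
#' matching rows for the same (band, group) are summed, and optional
#' per-subject offsets and a trial-level dB shift (behavioural
#' confound) are added.
#'
#' @param cfg a [study_config()]
#' @param texture,condition trial labels
#' @param subject_offsets optional data.frame (`band`, `group`,
#'   `texture`, `offset_db`)
#' @param extra_db scalar dB added to every effect row (trial-level
#'   confound; 0 by default)
#' @return data.frame `band`, `group`, `erd_db`
#' @export
erd_for_trial <- function(cfg, texture, condition,
                          subject_offsets = NULL, extra_db = 0) {
  tab <- cfg$erd_db
  hit <- (tab$texture == "*" | tab$texture == texture) &
    (tab$condition == "*" | tab$condition == condition)
  tab <- tab[hit, , drop = FALSE]
  if (!nrow(tab))
    return(data.frame(band = character(0), group = character(0),
                      erd_db = numeric(0)))
  agg <- stats::aggregate(erd_db ~ band + group, tab, sum)
  if (!is.null(subject_offsets)) {
    off <- subject_offsets[subject_offsets$texture == texture, ]
    m <- match(paste(agg$band, agg$group),
               paste(off$band, off$group))
    agg$erd_db <- agg$erd_db + ifelse(is.na(m), 0, off$offset_db[m])
  }
  agg$erd_db <- agg$erd_db + extra_db
  agg
}

#' Simulate EEG for one trial slot
#'
#' Produces a channels x samples segment covering one trial "slot"
#' (baseline + indicator + exploration + inter-trial interval) at
#' `cfg$fs_eeg`: pink (1/f) background noise on every channel, plus
#' band-limited oscillations (alpha, beta) on the designated channel
#' groups. From the ground-truth movement onset until the end of the
#' exploration period, the oscillation amplitude is scaled by
#' `10^(erd_db/20)` (raised-cosine ramp of 150 ms), so the log-ratio
#' ERSP of the segment recovers `erd_db`. Oscillator phase is random
#' per channel and trial. Uses the session RNG.
#'
#' @param cfg a [study_config()]
#' @param truth one-row ground-truth record from
#'   [simulate_touch_trial()] (uses `onset_ms`)
#' @param montage montage data.frame
#' @param groups named list of channel groups ([channel_groups()])
#' @param erd_eff effect table from [erd_for_trial()]; groups must
#'   exist in `groups`
#' @param noise include the 1/f background (callers assembling a
#'   whole recording may add noise once, in a single pass)
#' @return matrix `n_channels x n_samples` (microvolts); attribute
#'   `"cue_offset_s"` gives the go-cue position within the slot
#' @export
simulate_eeg_trial <- function(cfg, truth, montage, groups, erd_eff,
                               noise = TRUE) {
  if (nrow(montage) < 2)
    stop_atersp("config", "montage must have >= 2 channels")
  fs <- cfg$fs_eeg
  slot_s <- cfg$baseline_s + cfg$cue_s + cfg$explore_s + cfg$iti_s
  n <- as.integer(round(slot_s * fs))
  t <- (seq_len(n) - 1) / fs
  cue_at <- cfg$baseline_s + cfg$cue_s
  eff_start <- cue_at + truth$onset_ms / 1000
  eff_end <- cue_at + cfg$explore_s

  eeg <- if (noise) {
    one_over_f_noise(n, nrow(montage), fs,
                     amp_scale_from_db(cfg$noise_db))
  } else {
    matrix(0, nrow(montage), n)
  }
  rownames(eeg) <- montage$label

  ramp <- 0.15
  w <- numeric(n)                     # 0 before onset, 1 during effect
  w[t >= eff_start + ramp & t <= eff_end] <- 1
  ris <- t >= eff_start & t < eff_start + ramp
  w[ris] <- 0.5 * (1 - cos(pi * (t[ris] - eff_start) / ramp))
  fal <- t > eff_end & t < eff_end + ramp
  w[fal] <- 0.5 * (1 + cos(pi * (t[fal] - eff_end) / ramp))

  band_freq <- c(alpha = cfg$alpha_hz, beta = cfg$beta_hz)
  band_amp <- c(alpha = cfg$alpha_amp_uV, beta = cfg$beta_amp_uV)
  if (nrow(erd_eff)) {
    for (i in seq_len(nrow(erd_eff))) {
      grp <- erd_eff$group[i]
      if (is.null(groups[[grp]]))
        stop_atersp("config", "channel group '%s' not in montage groups", grp)
      chans <- match(groups[[grp]], montage$label)
      if (anyNA(chans))
        stop_atersp("config", "group '%s' names unknown channels", grp)
      f0 <- band_freq[[erd_eff$band[i]]]
      amp <- band_amp[[erd_eff$band[i]]]
      g <- amp_scale_from_db(erd_eff$erd_db[i])
      env <- amp * (1 + (g - 1) * w)
      for (ch in chans) {
        phi <- stats::runif(1, 0, 2 * pi)
        eeg[ch, ] <- eeg[ch, ] + env * sin(2 * pi * f0 * t + phi)
      }
    }
  }
  attr(eeg, "cue_offset_s") <- cue_at
  eeg
}
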