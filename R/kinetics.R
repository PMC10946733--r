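#' Block-average a sampled trace
#'
#' Reduces a series (or each column of a matrix/data.frame) to
#' `target_rate` by taking the arithmetic mean of consecutive
#' non-overlapping blocks of `fs / target_rate` samples. A final
#' partial block is truncated.
#'
#' @param x numeric vector, matrix or data.frame (samples in rows)
#' @param fs input sampling rate, Hz
#' @param target_rate output rate, Hz; must divide `fs`
#' @return same shape as `x` with `floor(n * target_rate / fs)` rows
#' @export
block_average <- function(x, fs, target_rate = 20) {
  if (target_rate > fs)
    stop_atersp("input", "target_rate (%g) exceeds fs (%g)", target_rate, fs)
  if (fs %% target_rate != 0)
    stop_atersp("input", "fs (%g) is not divisible by target_rate (%g)",
                fs, target_rate)
  k <- fs %/% target_rate
  if (is.data.frame(x)) {
    out <- as.data.frame(lapply(x, block_average, fs = fs,
                                target_rate = target_rate))
    names(out) <- names(x)
    return(out)
  }
  if (is.matrix(x)) {
    m <- nrow(x) %/% k
    if (m == 0) stop_atersp("input", "trace shorter than one block")
    a <- array(x[seq_len(m * k), , drop = FALSE], c(k, m, ncol(x)))
    out <- matrix(colMeans(a), m, ncol(x))
    colnames(out) <- colnames(x)
    return(out)
  }
  m <- length(x) %/% k
  if (m == 0) stop_atersp("input", "trace shorter than one block")
  colMeans(matrix(x[seq_len(m * k)], nrow = k))
}

#' Touch kinetics from block-averaged six-axis forces
#'
#' Inverts the force-plate mechanics to per-sample finger kinetics:
#' load in grams-force (`|Fz| / g0 * 1000`), tangential friction force
#' (`sqrt(Fx^2 + Fy^2)`, N), contact position from the centre of
#' pressure under static equilibrium (`x = (-My - Fx*h) / Fz`,
#' `y = (Mx - Fy*h) / Fz`, in mm, with plate-thickness correction `h`),
#' and movement speed from successive positions (mm/s; the first sample
#' is 0). Samples where `|Fz|` is below the contact threshold get
#' undefined (NA) position and speed rather than raising an error.
#'
#' @param rec data.frame with columns `t_ms`, `Fx_N`..`Mz_Nm`, sampled
#'   at `fs` (20 Hz after [block_average()])
#' @param fs sampling rate of `rec`, Hz
#' @param plate_h_m plate surface height above the sensor origin, m;
#'   set 0 for the uncorrected textbook form
#' @param contact_thresh_n minimum |Fz| (N) regarded as contact
#' @return data.frame `t_ms`, `x_mm`, `y_mm`, `friction_n`, `load_g`,
#'   `speed_mms`
#' @export
compute_kinetics <- function(rec, fs = 20, plate_h_m = 0.003,
                             contact_thresh_n = 0.05) {
  need <- c("t_ms", "Fx_N", "Fy_N", "Fz_N", "Mx_Nm", "My_Nm")
  if (!all(need %in% names(rec)))
    stop_atersp("input", "kinetics input lacks columns: %s",
                paste(setdiff(need, names(rec)), collapse = ", "))
  fz <- rec$Fz_N
  contact <- abs(fz) >= contact_thresh_n
  load_g <- newton_to_gram(fz)
  friction <- sqrt(rec$Fx_N^2 + rec$Fy_N^2)
  x <- ifelse(contact, 1000 * (-rec$My_Nm - rec$Fx_N * plate_h_m) / fz, NA_real_)
  y <- ifelse(contact, 1000 * (rec$Mx_Nm - rec$Fy_N * plate_h_m) / fz, NA_real_)
  speed <- c(0, sqrt(diff(x)^2 + diff(y)^2) * fs)
  data.frame(t_ms = rec$t_ms, x_mm = x, y_mm = y,
             friction_n = friction, load_g = load_g, speed_mms = speed)
}

#' Find local maxima with height, prominence and distance constraints
#'
#' Minimal peak finder with the semantics of the common scientific
#' peak-picking routines: a peak is a sample strictly greater than both
#' neighbours; `height` is an absolute threshold on the peak value;
#' `prominence` is the peak height above the higher of the two flanking
#' minima (each flank extends to the nearest sample exceeding the peak,
#' or the trace edge); `distance` greedily suppresses smaller peaks
#' closer than the given sample spacing to a larger one.
#'
#' @param x numeric vector (NAs treated as -Inf)
#' @param height minimum peak value
#' @param prominence minimum prominence, trace units
#' @param distance minimum separation in samples (1 = no constraint)
#' @return integer vector of peak indices, increasing
#' @export
find_peaks <- function(x, height = -Inf, prominence = 0, distance = 1) {
  x <- as.numeric(x)
  x[!is.finite(x)] <- -Inf
  n <- length(x)
  if (n < 3) return(integer(0))
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  idx <- idx[x[idx] >= height]
  if (!length(idx)) return(integer(0))
  if (prominence > 0) {
    prom <- vapply(idx, function(i) {
      l <- i - 1
      lmin <- x[i]
      while (l >= 1 && x[l] <= x[i]) { lmin <- min(lmin, x[l]); l <- l - 1 }
      r <- i + 1
      rmin <- x[i]
      while (r <= n && x[r] <= x[i]) { rmin <- min(rmin, x[r]); r <- r + 1 }
      # flank reaching the trace edge without a higher sample: use that min
      x[i] - max(lmin, rmin)
    }, numeric(1))
    idx <- idx[prom >= prominence]
  }
  if (distance > 1 && length(idx) > 1) {
    keep <- rep(TRUE, length(idx))
    ord <- order(-x[idx])
    for (j in ord) {
      if (!keep[j]) next
      too_close <- keep & abs(idx - idx[j]) < distance & seq_along(idx) != j
      keep[too_close & x[idx] <= x[idx[j]]] <- FALSE
    }
    idx <- idx[keep]
  }
  sort(idx)
}

#' Detect movement onset from a kinetics trace
#'
#' Follows the velocity-peak rule: signed per-axis velocities are
#' computed by first differences inside the detection window
#' (-200..4000 ms relative to the go cue); for each axis the first
#' local maximum of `v` with height at least `max(v)/2`, and the first
#' local maximum of `-v` with height at least `|min(v)|/2`, are
#' candidate onsets (peak prominence 1 trace unit, minimum separation
#' 1 sample); the earliest candidate is the onset. Returns `NA` when no
#' axis yields a candidate (e.g. a flat trace). A scalar-speed variant
#' (`mode = "speed"`) applies the same rule to the nonnegative speed
#' trace.
#'
#' @param trace kinetics data.frame from [compute_kinetics()], `t_ms`
#'   relative to the go cue
#' @param window detection window in ms relative to the cue
#' @param prominence,distance peak constraints (trace units, samples)
#' @param mode `"per_axis"` (default) or `"speed"`
#' @return onset time in ms relative to the cue, or `NA_real_`
#' @export
detect_movement_onset <- function(trace, window = c(-200, 4000),
                                  prominence = 1, distance = 1,
                                  mode = c("per_axis", "speed")) {
  mode <- match.arg(mode)
  sel <- trace$t_ms >= window[1] & trace$t_ms <= window[2]
  if (sum(sel) < 3) return(NA_real_)
  t <- trace$t_ms[sel]
  rate <- 1000 / stats::median(diff(t))
  vel_of <- function(p) c(NA_real_, diff(p)) * rate  # mm/s
  signals <- if (mode == "per_axis") {
    list(vel_of(trace$x_mm[sel]), vel_of(trace$y_mm[sel]))
  } else {
    list(trace$speed_mms[sel])
  }
  cand <- numeric(0)
  for (v in signals) {
    v[!is.finite(v)] <- 0
    for (s in list(v, -v)) {
      top <- max(s)
      if (top <= 0) next
      pk <- find_peaks(s, height = top / 2, prominence = prominence,
                       distance = distance)
      if (length(pk)) cand <- c(cand, t[pk[1]])
    }
  }
  if (!length(cand)) NA_real_ else min(cand)
}

#' Per-trial quality control and median summaries
#'
#' Applies the trial-rejection rules and computes the per-trial median
#' covariates. Flags: `no_trigger` when the go-cue event is missing;
#' `baseline_movement` when any speed sample before the cue exceeds the
#' stillness threshold; `late_onset` when the detected onset is
#' undefined or more than `onset_max_ms` after the cue (strictly
#' greater). A trial is accepted iff it has no flags; median speed,
#' friction and load are computed from movement onset to the end of the
#' exploration period for every trial with a defined onset.
#'
#' @param trials list of per-trial lists with elements `trace` (20-Hz
#'   kinetics, `t_ms` relative to cue), `onset_ms` (from
#'   [detect_movement_onset()]), `cue_present` (logical) and label
#'   fields `subject`, `trial`, `block`, `texture`, `condition`
#' @param baseline_speed_thresh_mms stillness threshold, mm/s
#' @param onset_max_ms latest acceptable onset, ms after cue
#' @param trial_end_ms end of the exploration period, ms after cue
#' @return data.frame, one row per trial: ids, labels, `onset_ms`,
#'   `median_speed_mms`, `median_friction_n`, `median_load_g`,
#'   `qc_flags` (comma-joined), `accepted`
#' @export
qc_and_summarise <- function(trials, baseline_speed_thresh_mms = 5,
                             onset_max_ms = 400, trial_end_ms = 4000) {
  if (!length(trials)) stop_atersp("input", "empty trial list")
  rows <- lapply(trials, function(tr) {
    flags <- character(0)
    if (!isTRUE(tr$cue_present)) flags <- c(flags, "no_trigger")
    onset <- tr$onset_ms
    med <- c(speed = NA_real_, friction = NA_real_, load = NA_real_)
    if (isTRUE(tr$cue_present) && !is.null(tr$trace)) {
      base <- tr$trace$t_ms < 0
      if (any(tr$trace$speed_mms[base] > baseline_speed_thresh_mms,
              na.rm = TRUE))
        flags <- c(flags, "baseline_movement")
      if (is.na(onset) || onset > onset_max_ms)
        flags <- c(flags, "late_onset")
      if (!is.na(onset)) {
        win <- tr$trace$t_ms >= onset & tr$trace$t_ms <= trial_end_ms
        med <- c(speed = stats::median(tr$trace$speed_mms[win], na.rm = TRUE),
                 friction = stats::median(tr$trace$friction_n[win], na.rm = TRUE),
                 load = stats::median(tr$trace$load_g[win], na.rm = TRUE))
      }
    } else {
      flags <- unique(c(flags, "no_trigger"))
      onset <- NA_real_
    }
    data.frame(subject = tr$subject %||% NA, trial = tr$trial %||% NA,
               block = tr$block %||% NA,
               texture = tr$texture %||% NA_character_,
               condition = tr$condition %||% NA_character_,
               onset_ms = onset,
               median_speed_mms = med[["speed"]],
               median_friction_n = med[["friction"]],
               median_load_g = med[["load"]],
               qc_flags = paste(flags, collapse = ","),
               accepted = !length(flags))
  })
  do.call(rbind, rows)
}

#' Z-score exclusion of behavioural outlier trials
#'
#' Within each (subject, block, texture) group of accepted trials,
#' computes z-scores (sample SD, n-1) for median speed, friction and
#' load; a trial whose |z| strictly exceeds 2 on any measure gains the
#' `zscore_outlier` flag and is rejected. Flags are computed in a
#' single pass (no iterative re-exclusion). Groups with fewer than two
#' accepted trials, or measures with zero SD (within numerical
#' tolerance relative to the measure's magnitude), exclude nothing.
#'
#' @param touch_trials data.frame from [qc_and_summarise()]
#' @param group_cols grouping columns
#' @param z_max exclusion bound (strict inequality)
#' @return `touch_trials` with updated `qc_flags` and `accepted`
#' @export
zscore_exclude <- function(touch_trials,
                           group_cols = c("subject", "block", "texture"),
                           z_max = 2) {
  tt <- touch_trials
  key <- interaction(tt[group_cols], drop = TRUE)
  measures <- c("median_speed_mms", "median_friction_n", "median_load_g")
  for (g in levels(key)) {
    idx <- which(key == g & tt$accepted)
    if (length(idx) < 2) next
    out <- rep(FALSE, length(idx))
    for (m in measures) {
      v <- tt[[m]][idx]
      s <- stats::sd(v)
      # zero SD within numerical tolerance: z-scores undefined
      if (!is.finite(s) || s <= 1e-10 * max(abs(v), 1)) next
      out <- out | abs((v - mean(v)) / s) > z_max
    }
    if (any(out)) {
      hit <- idx[out]
      tt$qc_flags[hit] <- ifelse(nzchar(tt$qc_flags[hit]),
                                 paste0(tt$qc_flags[hit], ",zscore_outlier"),
                                 "zscore_outlier")
      tt$accepted[hit] <- FALSE
    }
  }
  tt
}

#' Sensor stream to per-trial touch covariates
#'
#' Convenience driver for one subject: epochs the continuous six-axis
#' recording around each go-cue event, block-averages to 20 Hz,
#' computes kinetics, detects movement onset, applies the QC rules and
#' the z-score exclusion, and returns the touch-trial table.
#'
#' @param sensor continuous sensor data.frame (`t_ms` on the shared
#'   recording clock, `Fx_N`..`Mz_Nm`)
#' @param events events data.frame: `trial`, `block`, `cue_time_ms`
#'   (NA = missing trigger), `texture`, `condition`
#' @param fs_sensor sensor sampling rate, Hz
#' @param pre_s,explore_s seconds before the cue (baseline + indicator)
#'   and exploration duration
#' @param subject subject id copied into the table
#' @param plate_h_m,contact_thresh_n see [compute_kinetics()]
#' @param baseline_speed_thresh_mms,onset_max_ms see [qc_and_summarise()]
#' @param onset_mode see [detect_movement_onset()]
#' @param zscore logical; apply [zscore_exclude()]
#' @return touch-trial data.frame (one row per event)
#' @export
process_sensor <- function(sensor, events, fs_sensor, pre_s = 5,
                           explore_s = 4, subject = 1,
                           plate_h_m = 0.003, contact_thresh_n = 0.05,
                           baseline_speed_thresh_mms = 5,
                           onset_max_ms = 400,
                           onset_mode = "per_axis", zscore = TRUE) {
  tvec <- sensor$t_ms
  smat <- as.matrix(sensor[c("Fx_N", "Fy_N", "Fz_N", "Mx_Nm", "My_Nm",
                             "Mz_Nm")])
  trials <- lapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    base <- list(subject = subject, trial = ev$trial, block = ev$block,
                 texture = ev$texture, condition = ev$condition)
    if (is.na(ev$cue_time_ms)) {
      return(c(base, list(cue_present = FALSE, trace = NULL,
                          onset_ms = NA_real_)))
    }
    t0 <- ev$cue_time_ms - pre_s * 1000
    t1 <- ev$cue_time_ms + explore_s * 1000
    sel <- which(tvec >= t0 & tvec < t1)
    seg20 <- block_average(smat[sel, , drop = FALSE], fs_sensor, 20)
    # block-averaged time stamps are block centres
    t20 <- block_average(tvec[sel], fs_sensor, 20) - ev$cue_time_ms
    seg20 <- cbind(t_ms = t20, as.data.frame(seg20))
    kin <- compute_kinetics(seg20, fs = 20, plate_h_m = plate_h_m,
                            contact_thresh_n = contact_thresh_n)
    onset <- detect_movement_onset(kin, mode = onset_mode)
    c(base, list(cue_present = TRUE, trace = kin, onset_ms = onset))
  })
  tt <- qc_and_summarise(trials,
                         baseline_speed_thresh_mms = baseline_speed_thresh_mms,
                         onset_max_ms = onset_max_ms,
                         trial_end_ms = explore_s * 1000)
  if (zscore) tt <- zscore_exclude(tt)
  tt
}
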