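#' Simulate one subject's recordings with ground truth
#'
#' Generates, for one subject: the trial plan (texture x estimation
#' cells spread round-robin over blocks, order shuffled within block),
#' deliberate QC violations at the configured rate, the continuous
#' six-axis sensor stream, the continuous multichannel EEG (trials laid
#' out in fixed-length slots after a 1-s lead-in), go-cue events,
#' subjective ratings for estimation trials, and the ground-truth
#' table. All draws derive from `cfg$seed` and the subject index, so
#' output is bit-reproducible for an identical configuration.
#'
#' When `cfg$confound_db_per_unit` is nonzero, each trial's oscillation
#' power is additionally shifted by that many dB per standardised unit
#' of the trial's friction+load sum (z-scored within subject), coupling
#' band power to touch behaviour at the single-trial level.
#'
#' @param cfg a [study_config()]
#' @param subject subject index (1-based)
#' @param montage,groups optional precomputed montage and channel
#'   groups (defaults derived from `cfg$n_channels`)
#' @param eeg logical; simulate EEG (set `FALSE` for sensor-only runs)
#' @return list: `subject`, `montage`, `groups`, `sensor`, `events`,
#'   `truth`, `ratings`, `eeg` (channels x samples matrix or NULL),
#'   `fs_eeg`, `fs_sensor`
#' @export
simulate_subject <- function(cfg, subject = 1, montage = NULL,
                             groups = NULL, eeg = TRUE) {
  set.seed(derive_seed(cfg$seed, subject))
  if (is.null(montage)) montage <- make_montage(cfg$n_channels)
  if (is.null(groups)) groups <- channel_groups(montage)

  load_off <- stats::rnorm(1, 0, cfg$load_subject_sd_g)
  speed_off <- stats::rnorm(1, 0, cfg$speed_subject_sd_mms)
  rating_off <- stats::rnorm(length(cfg$ratings_mean), 0,
                             cfg$ratings_subject_sd)
  names(rating_off) <- names(cfg$ratings_mean)

  # per-subject ERD variability: one offset per (band, group, texture)
  eff_keys <- unique(cfg$erd_db[, c("band", "group")])
  offs <- do.call(rbind, lapply(TEXTURES, function(tx) {
    data.frame(band = eff_keys$band, group = eff_keys$group, texture = tx,
               offset_db = stats::rnorm(nrow(eff_keys), 0,
                                        cfg$erd_subject_sd_db))
  }))

  # trial plan
  plan <- expand.grid(rep_in_cell = seq_len(cfg$trials_per_cell),
                      condition = CONDITIONS, texture = TEXTURES,
                      stringsAsFactors = FALSE)
  plan$block <- ((plan$rep_in_cell - 1) %% cfg$n_blocks) + 1
  plan <- plan[order(plan$block), ]
  within_order <- unlist(lapply(split(seq_len(nrow(plan)), plan$block),
                                function(ix) ix[sample.int(length(ix))]))
  plan <- plan[within_order, ]
  n_tr <- nrow(plan)
  plan$trial <- seq_len(n_tr)
  plan$violation <- "none"
  n_viol <- round(cfg$violation_rate * n_tr)
  if (n_viol > 0) {
    vt <- rep(cfg$violation_types, length.out = n_viol)
    plan$violation[sample(n_tr, n_viol)] <- vt
  }

  slot_s <- cfg$baseline_s + cfg$cue_s + cfg$explore_s + cfg$iti_s
  lead_s <- 1
  cue_time <- (lead_s + (plan$trial - 1) * slot_s +
                 cfg$baseline_s + cfg$cue_s) * 1000

  # pass 1: touch trials
  touch <- lapply(seq_len(n_tr), function(i) {
    simulate_touch_trial(cfg, plan$texture[i], plan$condition[i],
                         violation = plan$violation[i],
                         load_offset_g = load_off,
                         speed_offset_mms = speed_off)
  })
  truth <- do.call(rbind, lapply(touch, `[[`, "truth"))
  truth <- cbind(data.frame(subject = subject, trial = plan$trial,
                            block = plan$block), truth)
  truth$cue_time_ms <- cue_time

  sensor <- do.call(rbind, lapply(seq_len(n_tr), function(i) {
    s <- touch[[i]]$sensor
    s$t_ms <- s$t_ms + cue_time[i]
    s
  }))

  events <- data.frame(trial = plan$trial, block = plan$block,
                       cue_time_ms = ifelse(plan$violation == "no_trigger",
                                            NA_real_, cue_time),
                       texture = plan$texture, condition = plan$condition)

  # trial-level behavioural confound on oscillation power (dB)
  conf_db <- numeric(n_tr)
  if (cfg$confound_db_per_unit != 0) {
    f_n <- truth$mu * gram_to_newton(truth$load_g)
    zsum <- as.numeric(scale(f_n)) + as.numeric(scale(truth$load_g))
    conf_db <- cfg$confound_db_per_unit * zsum
  }
  truth$confound_db <- conf_db

  eeg_mat <- NULL
  if (eeg) {
    fs <- cfg$fs_eeg
    slot_n <- as.integer(round(slot_s * fs))
    lead_n <- as.integer(round(lead_s * fs))
    # one noise pass for the whole recording, oscillations per slot
    eeg_mat <- one_over_f_noise(lead_n + n_tr * slot_n, nrow(montage),
                                fs, amp_scale_from_db(cfg$noise_db))
    rownames(eeg_mat) <- montage$label
    for (i in seq_len(n_tr)) {
      eff <- erd_for_trial(cfg, plan$texture[i], plan$condition[i],
                           subject_offsets = offs, extra_db = conf_db[i])
      seg <- simulate_eeg_trial(cfg, touch[[i]]$truth, montage, groups,
                                eff, noise = FALSE)
      cols <- lead_n + (i - 1) * slot_n + seq_len(slot_n)
      eeg_mat[, cols] <- eeg_mat[, cols] + seg
    }
  }

  # subjective ratings on estimation trials
  scale_of <- list(sensory = c("smooth", "soft"),
                   hedonic = c("pleasant", "comfort"))
  rrows <- lapply(seq_len(n_tr), function(i) {
    cond <- plan$condition[i]
    if (!cond %in% names(scale_of)) return(NULL)
    sc <- scale_of[[cond]]
    vals <- vapply(sc, function(s) {
      m <- cfg$ratings_mean[[s]][[plan$texture[i]]] + rating_off[[s]]
      if (plan$texture[i] == "hessian" && s %in% c("pleasant", "comfort"))
        m <- m + cfg$ratings_block_drift * (plan$block[i] - 1)
      min(100, max(0, stats::rnorm(1, m, cfg$ratings_sd)))
    }, numeric(1))
    data.frame(subject = subject, trial = plan$trial[i],
               block = plan$block[i], texture = plan$texture[i],
               condition = cond, scale = sc, value = vals)
  })
  ratings <- do.call(rbind, rrows)
  rownames(ratings) <- NULL

  list(subject = subject, montage = montage, groups = groups,
       sensor = sensor, events = events, truth = truth,
       ratings = ratings, eeg = eeg_mat,
       fs_eeg = cfg$fs_eeg, fs_sensor = cfg$fs_sensor)
}

#' Simulate a whole study in memory
#'
#' Calls [simulate_subject()] for every subject and returns the
#' collected data. Intended for small configurations; per-subject EEG
#' matrices are kept in memory, so large studies should instead be
#' streamed subject-by-subject (as [run_pipeline()] does) or written to
#' disk with [generate_study()].
#'
#' @param cfg a [study_config()]
#' @param eeg logical; simulate EEG
#' @return list: `cfg`, `montage`, `groups`, `subjects` (list of
#'   per-subject data), `truth` (row-bound ground truth)
#' @export
simulate_study <- function(cfg, eeg = TRUE) {
  montage <- make_montage(cfg$n_channels)
  groups <- channel_groups(montage)
  subjects <- lapply(seq_len(cfg$n_subjects), simulate_subject,
                     cfg = cfg, montage = montage, groups = groups,
                     eeg = eeg)
  list(cfg = cfg, montage = montage, groups = groups,
       subjects = subjects,
       truth = do.call(rbind, lapply(subjects, `[[`, "truth")))
}

#' Write a synthetic study to disk
#'
#' Generates every subject and writes the external fixture layout:
#' `sub-XX_eeg.tsv` (one column per channel, header row of channel
#' names, samples in rows), `sub-XX_sensor.tsv` (`t_ms`,
#' `Fx_N`..`Mz_Nm`), `sub-XX_events.tsv`, `sub-XX_ratings.tsv`, plus
#' study-level `montage.tsv`, `ground_truth.tsv` and `study.json`
#' (configuration echo and sign conventions: compression gives
#' `Fz < 0`; EEG in microvolts). EEG samples are written at microvolt
#' precision (3 decimals).
#'
#' @param cfg a [study_config()]
#' @param out_dir output directory (created if missing)
#' @param eeg logical; write EEG files
#' @return invisibly, the ground-truth table; files as side effect
#' @export
generate_study <- function(cfg, out_dir, eeg = TRUE) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_atersp("io", "cannot create output dir '%s'", out_dir)
  }
  montage <- make_montage(cfg$n_channels)
  groups <- channel_groups(montage)
  write_montage_tsv(montage, file.path(out_dir, "montage.tsv"))
  truths <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    sub <- simulate_subject(cfg, s, montage = montage, groups = groups,
                            eeg = eeg)
    tag <- sprintf("sub-%02d", s)
    write_tsv(sub$sensor, file.path(out_dir, paste0(tag, "_sensor.tsv")))
    write_tsv(sub$events, file.path(out_dir, paste0(tag, "_events.tsv")))
    if (!is.null(sub$ratings))
      write_tsv(sub$ratings, file.path(out_dir, paste0(tag, "_ratings.tsv")))
    if (eeg) {
      m <- as.data.frame(round(t(sub$eeg), 3))
      names(m) <- montage$label
      write_tsv(m, file.path(out_dir, paste0(tag, "_eeg.tsv")))
    }
    truths[[s]] <- sub$truth
  }
  truth <- do.call(rbind, truths)
  write_tsv(truth, file.path(out_dir, "ground_truth.tsv"))
  meta <- list(
    conventions = list(
      load_sign = "compression gives Fz < 0 at the sensor",
      eeg_units = "microvolts", moment_units = "newton-metres",
      cop = "x = (-My - Fx*h)/Fz, y = (Mx - Fy*h)/Fz"),
    fs_sensor = cfg$fs_sensor, fs_eeg = cfg$fs_eeg,
    n_subjects = cfg$n_subjects, trials_per_cell = cfg$trials_per_cell,
    plate_h_m = cfg$plate_h_m, seed = cfg$seed,
    groups = groups)
  jsonlite::write_json(meta, file.path(out_dir, "study.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(truth)
}
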