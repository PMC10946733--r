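# Shared fixtures, built in code.

# Small fast study configuration for pipeline-level tests.
tiny_study <- function(seed = 11, ...) {
  study_config(n_subjects = 3, trials_per_cell = 4, n_channels = 16,
               fs_eeg = 128, fs_sensor = 200, violation_rate = 0,
               seed = seed, ...)
}

# Single-channel epochs object wrapping a signal vector on the
# standard -5.5..5 s onset-locked time axis.
epochs_from_signal <- function(x, fs, n_channels = 1) {
  n <- length(x)
  dat <- array(rep(x, each = n_channels), c(1, n_channels, n))
  structure(list(data = dat,
                 t_ms = seq(-5.5 * 1000, by = 1000 / fs, length.out = n),
                 fs = fs,
                 labels = data.frame(subject = 1, trial = 1, block = 1,
                                     texture = "hessian",
                                     condition = "none", onset_ms = 250,
                                     median_speed_mms = 100,
                                     median_friction_n = 1,
                                     median_load_g = 150)),
            class = "eeg_epochs")
}

onset_locked_signal <- function(fs, f0 = 10, amp = 20, scale = 0.5,
                                phase = 1) {
  tm <- seq(-5.5, 5 - 1 / fs, 1 / fs)
  env <- ifelse(tm >= 0 & tm <= 4, scale, 1)
  amp * env * sin(2 * pi * f0 * tm + phase)
}

# Block-average + kinetics + onset for one simulated trial.
trial_onset <- function(cfg, tr) {
  s20 <- cbind(t_ms = block_average(tr$sensor$t_ms, cfg$fs_sensor, 20),
               as.data.frame(block_average(
                 as.matrix(tr$sensor[-1]), cfg$fs_sensor, 20)))
  kin <- compute_kinetics(s20, 20, plate_h_m = cfg$plate_h_m)
  detect_movement_onset(kin)
}

# Accepted-trial table with arbitrary kinetics medians, one row per
# cell repeated `reps` times (for design-matrix tests).
fake_trials <- function(reps = 2, seed = 1) {
  set.seed(seed)
  g <- expand.grid(rep = seq_len(reps),
                   condition = c("sensory", "hedonic", "none"),
                   texture = c("hessian", "silk"),
                   stringsAsFactors = FALSE)
  data.frame(subject = 1, trial = seq_len(nrow(g)), block = 1,
             texture = g$texture, condition = g$condition,
             onset_ms = 250,
             median_speed_mms = rnorm(nrow(g), 150, 20),
             median_friction_n = rnorm(nrow(g), 1, 0.2),
             median_load_g = rnorm(nrow(g), 150, 25),
             qc_flags = "", accepted = TRUE)
}

# Texture-effect analysis of one synthetic study: simulate each
# subject, run the touch/EEG chain, first-level GLM, one-sample
# second-level F, cluster threshold, and per-subject-texture cluster
# power. Alpha band only. Returns clusters, the scalp grid, and the
# extraction table.
texture_study_analysis <- function(scfg, image_hz = 16, k_min = 35,
                                   p_form = 0.001, connectivity = 18) {
  montage <- make_montage(scfg$n_channels)
  groups <- channel_groups(montage)
  grid <- scalp_grid(montage)
  cons <- vector("list", scfg$n_subjects)
  tex_means <- vector("list", scfg$n_subjects)
  img_t <- NULL
  for (s in seq_len(scfg$n_subjects)) {
    sub <- simulate_subject(scfg, s, montage = montage, groups = groups)
    tt <- process_sensor(sub$sensor, sub$events, scfg$fs_sensor,
                         pre_s = scfg$baseline_s + scfg$cue_s,
                         explore_s = scfg$explore_s, subject = s,
                         plate_h_m = scfg$plate_h_m)
    rec <- eeg_recording(sub$eeg, scfg$fs_eeg, montage)
    ep <- epoch_to_onsets(rec, tt, sub$events)
    ep <- common_average_reference(ep)
    ep <- amplitude_artifact_reject(ep, 500)
    bm <- band_maps(ep, bands = list(alpha = c(8, 12)))$alpha
    sti <- atersp:::scalp_time_images_smoothed(bm, grid,
                                               image_hz = image_hz)
    img_t <- sti$t_ms
    design <- build_design(ep$labels)
    con <- fit_first_level(array(sti$M, c(nrow(sti$M), sti$vshape)),
                           design,
                           paper_contrasts(design)["texture"])
    cons[[s]] <- con$texture
    cells <- atersp:::cell_label(ep$labels$texture, ep$labels$condition)
    hess <- colMeans(sti$M[cells %in% c("HH", "SH", "NH"), ,
                           drop = FALSE])
    silk <- colMeans(sti$M[cells %in% c("HS", "SS", "NS"), ,
                           drop = FALSE])
    tex_means[[s]] <- list(hessian = array(hess, sti$vshape),
                           silk = array(silk, sti$vshape))
  }
  sl <- second_level_F(cons, "one_sample")
  cl <- cluster_threshold(sl$F, sl$df, t_ms = img_t, p_form = p_form,
                          k_min = k_min, connectivity = connectivity)
  power <- extract_cluster_power(cl, tex_means)
  list(clusters = cl, grid = grid, montage = montage, groups = groups,
       power = power, Fmap = sl$F, df = sl$df)
}

# Pixel set within `radius_mm` of any electrode of a montage group,
# for cluster-overlap checks.
region_pixels <- function(grid, montage, labels, radius_mm = 15) {
  el <- grid$electrodes
  sel <- el$label %in% labels
  px <- expand.grid(x = grid$px_x, y = grid$px_y)
  hit <- rep(FALSE, nrow(px))
  for (i in which(sel)) {
    hit <- hit | (px$x - el$x_mm[i])^2 + (px$y - el$y_mm[i])^2 <=
      radius_mm^2
  }
  matrix(hit, grid$nx, grid$ny)
}
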