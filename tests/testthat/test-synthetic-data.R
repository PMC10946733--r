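test_that("noiseless trials obey exact friction-load coupling", {
  cfg <- study_config(sensor_noise_frac = 0, mu_friction =
                        c(hessian = 0.9, silk = 0.5),
                      mu_trial_cv = 0, load_mean_g = 100,
                      load_sd_g = 0,
                      load_condition_shift_g = c(sensory = 0,
                                                 hedonic = 0, none = 0),
                      seed = 1)
  set.seed(1)
  tr <- simulate_touch_trial(cfg, "silk")
  kin <- compute_kinetics(tr$sensor, fs = cfg$fs_sensor,
                          plate_h_m = cfg$plate_h_m)
  moving <- kin$speed_mms > 5 & is.finite(kin$speed_mms)
  ratio <- kin$friction_n[moving] / gram_to_newton(kin$load_g[moving])
  expect_lt(max(abs(ratio - 0.5)), 1e-12)
  expect_equal(tr$truth$load_g, 100)
  expect_error(simulate_touch_trial(cfg, "velvet"),
               class = "atersp_input_error")
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- study_config(seed = 3)
  set.seed(99)
  a <- simulate_touch_trial(cfg, "hessian")
  set.seed(99)
  b <- simulate_touch_trial(cfg, "hessian")
  expect_identical(a, b)

  cfg2 <- tiny_study(seed = 21)
  s1 <- simulate_subject(cfg2, 1)
  s2 <- simulate_subject(cfg2, 1)
  expect_identical(s1$sensor, s2$sensor)
  expect_identical(s1$eeg, s2$eeg)
  expect_identical(s1$truth, s2$truth)
})

test_that("friction and load correlate strongly across trials", {
  # Monte-Carlo check of the generator against mu * load coupling
  cfg <- study_config(fs_sensor = 100, seed = 8)
  set.seed(8)
  fl <- t(replicate(1000, {
    tr <- simulate_touch_trial(cfg, "hessian")
    c(tr$truth$mu * gram_to_newton(tr$truth$load_g), tr$truth$load_g)
  }))
  r <- cor(fl[, 1], fl[, 2])
  expect_gte(r, 0.7)
})

test_that("injected ERD scales post-onset oscillation power as stated", {
  mon <- make_montage(8)
  grp <- channel_groups(mon, k = 2, regions = "sensorimotor_left")
  cfg <- study_config(n_channels = 8, fs_eeg = 128, noise_db = -Inf,
                      seed = 1)
  truth <- data.frame(onset_ms = 250)

  # null case: erd 0 dB leaves the post/pre power ratio at one
  set.seed(5)
  eff0 <- data.frame(band = "alpha", group = "sensorimotor_left",
                     erd_db = 0)
  seg <- simulate_eeg_trial(cfg, truth, mon, grp, eff0)
  fs <- cfg$fs_eeg
  ch <- match(grp$sensorimotor_left[1], mon$label)
  cue <- (cfg$baseline_s + cfg$cue_s) * fs
  pre <- seg[ch, (cue - 3 * fs):(cue - 1 * fs)]
  post <- seg[ch, (cue + 1 * fs):(cue + 3.5 * fs)]
  expect_lt(abs(db_from_ratio(mean(post^2) / mean(pre^2))), 0.2)

  # closed-form dB arithmetic: amplitude 0.5 is -6.02 dB
  expect_equal(db_from_ratio(amp_scale_from_db(-6.02)^2), -6.02,
               tolerance = 1e-12)
  expect_equal(amp_scale_from_db(-6.0206), 0.5, tolerance = 1e-4)

  # noiseless -3.36 dB injection recovered by the package's own ERSP
  set.seed(6)
  eff <- data.frame(band = "alpha", group = "sensorimotor_left",
                    erd_db = -3.36)
  seg2 <- simulate_eeg_trial(cfg, truth, mon, grp, eff)
  # epoch the slot relative to the true onset (slot starts -5.25 s
  # before it, leaving ample edge margin for the alpha wavelets)
  onset_idx <- cue + round(0.25 * fs)
  n_ep <- round(10.5 * fs)
  ep <- structure(list(
    data = array(seg2[ch, seq_len(n_ep)], c(1, 1, n_ep)),
    t_ms = seq(-(onset_idx - 1) / fs * 1000, by = 1000 / fs,
               length.out = n_ep),
    fs = fs, labels = NULL), class = "eeg_epochs")
  bm <- band_maps(ep, bands = list(alpha = c(8, 12)))
  sel <- bm$alpha$t_ms >= 500 & bm$alpha$t_ms <= 3500
  expect_lt(abs(mean(bm$alpha$data[1, 1, sel]) + 3.36), 0.1)

  # unknown channel group is a labelled config error
  effx <- data.frame(band = "alpha", group = "nonexistent", erd_db = -1)
  expect_error(simulate_eeg_trial(cfg, truth, mon, grp, effx),
               class = "atersp_config_error")
})

test_that("generate_study writes the fixture tree with exact counts", {
  dir <- tempfile("study")
  cfg <- study_config(n_subjects = 2, trials_per_cell = 2,
                      n_channels = 4, fs_eeg = 64, fs_sensor = 100,
                      violation_rate = 0, seed = 13)
  truth <- generate_study(cfg, dir)
  files <- list.files(dir)
  for (f in c("montage.tsv", "ground_truth.tsv", "study.json",
              "sub-01_eeg.tsv", "sub-01_sensor.tsv", "sub-01_events.tsv",
              "sub-01_ratings.tsv", "sub-02_eeg.tsv"))
    expect_true(f %in% files, label = f)
  expect_equal(nrow(truth), 2 * 2 * 6)
  counts <- table(truth$texture, truth$condition, truth$subject)
  expect_true(all(counts == cfg$trials_per_cell))

  # bit-reproducibility: regeneration yields identical bytes
  dir2 <- tempfile("study")
  generate_study(cfg, dir2)
  for (f in c("sub-01_eeg.tsv", "sub-01_sensor.tsv", "ground_truth.tsv"))
    expect_identical(unname(tools::md5sum(file.path(dir, f))),
                     unname(tools::md5sum(file.path(dir2, f))))
  unlink(c(dir, dir2), recursive = TRUE)
})

test_that("QC keeps everything at 0% violations, rejects flagged trials", {
  # onset draws kept clear of the 400-ms boundary: the velocity-peak
  # detector carries a ~+25 ms sampling bias at 20 Hz, so true onsets
  # within one kinetics sample of the rule would be boundary cases
  cfg <- study_config(n_subjects = 1, trials_per_cell = 4,
                      n_channels = 4, fs_sensor = 200,
                      violation_rate = 0, load_sd_g = 5,
                      mu_trial_cv = 0.02,
                      onset_latency_sd_ms = 30, seed = 31)
  sub <- simulate_subject(cfg, 1, eeg = FALSE)
  tt <- process_sensor(sub$sensor, sub$events, cfg$fs_sensor,
                       pre_s = 5, explore_s = 4, subject = 1,
                       zscore = FALSE)
  expect_true(all(tt$accepted))

  cfgv <- study_config(n_subjects = 1, trials_per_cell = 6,
                       n_channels = 4, fs_sensor = 200,
                       violation_rate = 0.25,
                       onset_latency_mean_ms = 250,
                       onset_latency_sd_ms = 30, seed = 32)
  subv <- simulate_subject(cfgv, 1, eeg = FALSE)
  ttv <- process_sensor(subv$sensor, subv$events, cfgv$fs_sensor,
                        pre_s = 5, explore_s = 4, subject = 1,
                        zscore = FALSE)
  cmp <- merge(ttv, subv$truth[, c("trial", "violation")], by = "trial")
  expect_equal(!cmp$accepted, cmp$violation != "none")
})
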