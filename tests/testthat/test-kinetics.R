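test_that("block averaging reduces rate by non-overlapping means", {
  expect_equal(block_average(rep(2, 1000), 1000, 20), rep(2, 20))
  x <- c(1:50, rnorm(950))
  expect_equal(block_average(x, 1000, 20)[1], 25.5)
  # brute-force oracle on a random trace
  set.seed(42)
  y <- rnorm(1000)
  oracle <- vapply(seq_len(20), function(b)
    mean(y[((b - 1) * 50 + 1):(b * 50)]), numeric(1))
  expect_equal(block_average(y, 1000, 20), oracle, tolerance = 1e-12)
  # final partial block truncated
  expect_length(block_average(rnorm(1049), 1000, 20), 20)
  expect_error(block_average(1:10, 20, 50), class = "atersp_input_error")
  expect_error(block_average(1:10, 30, 20), class = "atersp_input_error")
})

test_that("kinetics invert the force-plate mechanics", {
  rec <- data.frame(t_ms = c(0, 50), Fx_N = c(0.3, 0.3),
                    Fy_N = c(0.4, 0.4), Fz_N = c(-2, -2),
                    Mx_Nm = c(0.06, 0.06), My_Nm = c(0.1, 0.1),
                    Mz_Nm = 0)
  kin <- compute_kinetics(rec, 20, plate_h_m = 0)
  expect_equal(kin$friction_n, c(0.5, 0.5))           # 3-4-5 triangle
  expect_equal(kin$x_mm, c(50, 50))                   # x = -My/Fz
  expect_equal(kin$y_mm, c(-30, -30))                 # y = Mx/Fz
  expect_equal(kin$load_g, rep(2 / 9.80665 * 1000, 2))

  # speed: (0,0) -> (3,4) mm over one 50-ms step is 100 mm/s
  rec2 <- data.frame(t_ms = c(0, 50), Fx_N = 0, Fy_N = 0,
                     Fz_N = c(-1, -1),
                     Mx_Nm = c(0, -4e-3), My_Nm = c(0, 3e-3), Mz_Nm = 0)
  kin2 <- compute_kinetics(rec2, 20, plate_h_m = 0)
  expect_equal(kin2$x_mm, c(0, 3))
  expect_equal(kin2$y_mm, c(0, 4))
  expect_equal(kin2$speed_mms, c(0, 100))

  # below contact threshold: undefined position, no error
  rec3 <- rec
  rec3$Fz_N <- c(-2, -0.01)
  kin3 <- compute_kinetics(rec3, 20)
  expect_true(is.na(kin3$x_mm[2]) && is.na(kin3$speed_mms[2]))
})

test_that("CoP recovery is exact on crafted point-load records", {
  # forward-model a known contact trajectory, then invert it
  set.seed(4)
  t <- seq(0, 2, by = 0.01)
  x <- 12 * sin(2 * pi * 1.5 * t)               # mm
  y <- -8 * cos(2 * pi * 1.1 * t)
  fz <- -(1.2 + 0.2 * sin(2 * pi * 0.4 * t))    # N, compression
  fx <- 0.5 * cos(2 * pi * 0.9 * t)
  fy <- 0.3 * sin(2 * pi * 0.7 * t)
  h <- 0.003
  rec <- data.frame(t_ms = t * 1000, Fx_N = fx, Fy_N = fy, Fz_N = fz,
                    Mx_Nm = (y / 1000) * fz + fy * h,
                    My_Nm = -(x / 1000) * fz - fx * h,
                    Mz_Nm = 0)
  kin <- compute_kinetics(rec, fs = 100, plate_h_m = h)
  expect_lt(max(abs(kin$x_mm - x)), 1e-9)
  expect_lt(max(abs(kin$y_mm - y)), 1e-9)
  # omitting the plate term biases x by exactly +Fx*h/Fz (in mm)
  kin0 <- compute_kinetics(rec, fs = 100, plate_h_m = 0)
  expect_equal(kin0$x_mm - x, 1000 * fx * h / fz, tolerance = 1e-9)

  # generator trials share the convention: stationary baseline CoP is
  # recovered as a constant to machine precision in the noiseless case
  cfg <- study_config(sensor_noise_frac = 0, seed = 2)
  set.seed(9)
  tr <- simulate_touch_trial(cfg, "silk")
  kr <- compute_kinetics(tr$sensor, fs = cfg$fs_sensor,
                         plate_h_m = cfg$plate_h_m)
  base <- tr$sensor$t_ms < -1000
  expect_lt(max(abs(kr$x_mm[base] - kr$x_mm[which(base)[1]])), 1e-9)
})

test_that("peak finder honours height, prominence and distance", {
  x <- c(0, 1, 0, 3, 0, 2, 0)
  expect_equal(find_peaks(x), c(2L, 4L, 6L))
  expect_equal(find_peaks(x, height = 2), c(4L, 6L))
  expect_equal(find_peaks(x, height = 2, distance = 3), 4L)
  # prominence: middle peak sits on a pedestal
  y <- c(0, 5, 4.6, 5.2, 0)
  expect_equal(find_peaks(y, prominence = 1), 4L)
  expect_equal(find_peaks(y, prominence = 0.3), c(2L, 4L))
  expect_length(find_peaks(rep(1, 10)), 0)

  # property: agrees with a brute-force prominence oracle
  oracle_prom <- function(x, i) {
    n <- length(x)
    lmin <- x[i]; j <- i - 1
    while (j >= 1 && x[j] <= x[i]) { lmin <- min(lmin, x[j]); j <- j - 1 }
    rmin <- x[i]; j <- i + 1
    while (j <= n && x[j] <= x[i]) { rmin <- min(rmin, x[j]); j <- j + 1 }
    x[i] - max(lmin, rmin)
  }
  set.seed(7)
  for (rep in 1:25) {
    z <- cumsum(rnorm(60))
    got <- find_peaks(z, prominence = 0.8)
    cand <- which(diff(sign(diff(z))) == -2) + 1L
    want <- cand[vapply(cand, function(i) oracle_prom(z, i),
                        numeric(1)) >= 0.8]
    expect_equal(got, want)
  }
})

test_that("movement onset is the earliest qualifying velocity peak", {
  t <- seq(-200, 4000, by = 50)
  flat <- data.frame(t_ms = t, x_mm = 0, y_mm = 0, friction_n = 0,
                     load_g = 100, speed_mms = 0)
  expect_true(is.na(detect_movement_onset(flat)))

  # smooth positive bump in x-velocity peaking at +200 ms
  vx <- 80 * exp(-((t - 200) / 150)^2)
  x <- cumsum(vx) * 0.05
  bump <- data.frame(t_ms = t, x_mm = x, y_mm = 0, friction_n = 0,
                     load_g = 100, speed_mms = c(0, abs(diff(x)) * 20))
  on <- detect_movement_onset(bump)
  expect_lt(abs(on - 200), 51)

  # negative-going y extremum at 150 ms before a positive x peak at 300
  vy <- -90 * exp(-((t - 150) / 120)^2)
  vx2 <- 90 * exp(-((t - 300) / 120)^2)
  tr <- data.frame(t_ms = t, x_mm = cumsum(vx2) * 0.05,
                   y_mm = cumsum(vy) * 0.05, friction_n = 0,
                   load_g = 100,
                   speed_mms = sqrt(vx2^2 + vy^2))
  on2 <- detect_movement_onset(tr)
  expect_lt(abs(on2 - 150), 51)
})

test_that("QC rules flag and reject per the 400-ms and stillness rules", {
  t <- seq(-5000, 4000, by = 50)
  mk_trace <- function(onset_ms, baseline_speed = 0) {
    sp <- ifelse(t < 0, baseline_speed,
                 ifelse(t >= onset_ms, 120, 0))
    data.frame(t_ms = t, x_mm = 0, y_mm = 0, friction_n = 0.9,
               load_g = 140, speed_mms = sp)
  }
  trials <- list(
    list(subject = 1, trial = 1, block = 1, texture = "silk",
         condition = "none", cue_present = TRUE,
         trace = mk_trace(401), onset_ms = 401),
    list(subject = 1, trial = 2, block = 1, texture = "silk",
         condition = "none", cue_present = TRUE,
         trace = mk_trace(399), onset_ms = 399),
    list(subject = 1, trial = 3, block = 1, texture = "silk",
         condition = "none", cue_present = FALSE, trace = NULL,
         onset_ms = NA_real_),
    list(subject = 1, trial = 4, block = 1, texture = "silk",
         condition = "none", cue_present = TRUE,
         trace = mk_trace(300, baseline_speed = 30), onset_ms = 300))
  tt <- qc_and_summarise(trials)
  expect_equal(tt$qc_flags, c("late_onset", "", "no_trigger",
                              "baseline_movement"))
  expect_equal(tt$accepted, c(FALSE, TRUE, FALSE, FALSE))
  # medians equal a sort-based oracle over onset..end
  tr2 <- trials[[2]]$trace
  win <- tr2$t_ms >= 399 & tr2$t_ms <= 4000
  med <- function(v) sort(v)[ceiling(length(v) / 2):ceiling((length(v) + 1) / 2)]
  expect_equal(tt$median_speed_mms[2],
               mean(med(tr2$speed_mms[win])))
  expect_equal(tt$median_load_g[2], 140)
  expect_error(qc_and_summarise(list()), class = "atersp_input_error")
})

test_that("z-score exclusion is strict, single-pass and degenerate-safe", {
  base <- data.frame(subject = 1, trial = 1:10, block = 1,
                     texture = "silk", condition = "none",
                     onset_ms = 250, median_speed_mms = 100,
                     median_friction_n = 1, median_load_g = 150,
                     qc_flags = "", accepted = TRUE)
  # 9 identical + 1 distinct: |z| = 9/sqrt(10) / sqrt(0.9) = 2.846 > 2
  tt <- base
  tt$median_load_g <- c(rep(150, 9), 200)
  out <- zscore_exclude(tt)
  expect_equal(out$accepted, c(rep(TRUE, 9), FALSE))
  expect_match(out$qc_flags[10], "zscore_outlier")

  # all identical: SD = 0, nothing excluded
  expect_true(all(zscore_exclude(base)$accepted))

  # value at exactly |z| = 2 is kept (strict inequality)
  tt9 <- base[1:9, ]
  tt9$median_load_g <- 150 + c(-1, rep(0, 7), 1)   # z(+-1) = 2 exactly
  z <- abs(tt9$median_load_g - mean(tt9$median_load_g)) /
    sd(tt9$median_load_g)
  expect_equal(max(z), 2)
  expect_true(all(zscore_exclude(tt9)$accepted))

  # groups of one pass through
  tt1 <- base[1, ]
  expect_true(zscore_exclude(tt1)$accepted)
})

test_that("friction is invariant to rotation of the tangential force", {
  set.seed(3)
  for (i in 1:10) {
    fx <- rnorm(5)
    fy <- rnorm(5)
    th <- runif(1, 0, 2 * pi)
    rec <- function(a, b) data.frame(
      t_ms = seq(0, 200, 50), Fx_N = a, Fy_N = b, Fz_N = -2,
      Mx_Nm = 0, My_Nm = 0, Mz_Nm = 0)
    k1 <- compute_kinetics(rec(fx, fy), 20)
    k2 <- compute_kinetics(rec(cos(th) * fx - sin(th) * fy,
                               sin(th) * fx + cos(th) * fy), 20)
    expect_equal(k1$friction_n, k2$friction_n, tolerance = 1e-12)
  }
})
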