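#' Simulate one six-axis touch-sensor trial
#'
#' Generates force/torque traces for a single trial window around the
#' go cue: the finger rests stationary on the texture through the
#' baseline and indicator periods, then performs smooth back-and-forth
#' exploratory strokes starting at a drawn onset latency. The traces
#' satisfy the mechanical model the kinetics module inverts:
#' compression gives `Fz < 0`; the tangential force opposes the finger
#' velocity with magnitude `mu * |Fz|` (Amontons coupling, plus optional
#' multiplicative noise); moments encode the contact point under static
#' equilibrium, `My = -x*Fz - Fx*h` and `Mx = y*Fz + Fy*h` with plate
#' thickness `h`, so centre-of-pressure recovery is exact when the
#' noise fraction is zero.
#'
#' The ground-truth movement onset is defined as the time of the first
#' velocity peak of the initial stroke (a quarter stroke period after
#' motion begins), which is the event the velocity-peak onset detector
#' estimates and the event EEG effects are locked to.
#'
#' Uses the session RNG; seed with [set.seed()] (study-level drivers
#' derive per-subject seeds from `cfg$seed`).
#'
#' @param cfg a [study_config()]
#' @param texture `"hessian"` or `"silk"`
#' @param condition estimation condition label (copied to ground truth)
#' @param violation one of `"none"`, `"late_onset"`,
#'   `"baseline_movement"`, `"no_trigger"`, `"zscore_outlier"`;
#'   deliberately violating trials are generated for QC testing and
#'   flagged in the returned ground-truth record
#' @param load_offset_g,speed_offset_mms subject-level additive offsets
#' @return list with `sensor` (data.frame `t_ms` relative to the go
#'   cue, `Fx_N`..`Mz_Nm`) and `truth` (one-row data.frame: labels,
#'   `onset_ms`, `move_start_ms`, `mu`, `load_g`, `speed_peak_mms`,
#'   `violation`)
#' @export
simulate_touch_trial <- function(cfg, texture, condition = "none",
                                 violation = "none",
                                 load_offset_g = 0,
                                 speed_offset_mms = 0) {
  if (!texture %in% TEXTURES)
    stop_atersp("input", "unknown texture label '%s'", texture)
  fs <- cfg$fs_sensor
  dt <- 1 / fs
  pre_s <- cfg$baseline_s + cfg$cue_s
  post_s <- 1
  n <- as.integer(round((pre_s + cfg$explore_s + post_s) * fs))
  t <- (seq_len(n) - 1) * dt - pre_s      # seconds relative to go cue
  frac <- cfg$sensor_noise_frac

  # onset latency: time of the first velocity peak, relative to cue
  rise <- 1 / (4 * cfg$stroke_hz)
  lat <- if (violation == "late_onset") {
    stats::runif(1, 0.5, 0.7)
  } else {
    rnorm_trunc(1, cfg$onset_latency_mean_ms / 1000,
                cfg$onset_latency_sd_ms / 1000,
                max(0.15, rise + 0.02), 0.39)
  }
  t_start <- lat - rise

  # stroke kinematics: 1D oscillation along a random direction
  v_peak <- max(30, stats::rnorm(1, cfg$speed_mean_mms + speed_offset_mms,
                                 cfg$speed_sd_mms))
  theta <- stats::runif(1, 0, 2 * pi)
  u <- c(cos(theta), sin(theta))
  amp <- v_peak / (2 * pi * cfg$stroke_hz)   # mm
  moving <- t >= t_start & t <= cfg$explore_s
  stroke <- ifelse(moving,
                   amp * (1 - cos(2 * pi * cfg$stroke_hz * (t - t_start))),
                   ifelse(t > cfg$explore_s,
                          amp * (1 - cos(2 * pi * cfg$stroke_hz *
                                         (cfg$explore_s - t_start))),
                          0))
  p0 <- stats::runif(2, -10, 10)
  x <- p0[1] + stroke * u[1]
  y <- p0[2] + stroke * u[2]

  if (violation == "baseline_movement") {
    # a 0.6-s excursion in mid-baseline, peak speed ~ 40 mm/s
    tb <- -(pre_s / 2)
    dur <- 0.6
    inb <- t >= tb & t <= tb + dur
    bump <- numeric(n)
    bump[inb] <- 8 * sin(pi * (t[inb] - tb) / dur)^2
    phi <- stats::runif(1, 0, 2 * pi)
    x <- x + bump * cos(phi)
    y <- y + bump * sin(phi)
  }
  if (frac > 0) {
    x <- x + stats::rnorm(n, 0, 0.02)
    y <- y + stats::rnorm(n, 0, 0.02)
  }

  # load (grams-force) with slow physiological wander
  cond_shift <- cfg$load_condition_shift_g[condition]
  if (is.null(cond_shift) || is.na(cond_shift)) cond_shift <- 0
  load_g <- max(30, stats::rnorm(1, cfg$load_mean_g + load_offset_g +
                                   cond_shift, cfg$load_sd_g))
  if (violation == "zscore_outlier") load_g <- load_g * 3
  wander <- if (frac > 0)
    1 + 0.05 * sin(2 * pi * 0.3 * (t + pre_s) + stats::runif(1, 0, 2 * pi))
  else rep(1, n)
  fz <- -gram_to_newton(load_g * wander)

  # tangential force opposes the instantaneous velocity
  mu <- cfg$mu_friction[[texture]] *
    max(0.05, 1 + stats::rnorm(1, 0, cfg$mu_trial_cv))
  vx <- c(0, diff(x)) / dt
  vy <- c(0, diff(y)) / dt
  spd <- sqrt(vx^2 + vy^2)
  in_motion <- spd > 1                      # mm/s
  fmag <- mu * abs(fz) * (1 + if (frac > 0) stats::rnorm(n, 0, frac) else 0)
  ux <- ifelse(in_motion, -vx / pmax(spd, 1e-9), 0)
  uy <- ifelse(in_motion, -vy / pmax(spd, 1e-9), 0)
  fx <- fmag * ux
  fy <- fmag * uy
  if (frac > 0) {
    fx <- fx + stats::rnorm(n, 0, frac * 0.02)
    fy <- fy + stats::rnorm(n, 0, frac * 0.02)
  }

  # moments from the contact point (static equilibrium, plate height h)
  h <- cfg$plate_h_m
  x_m <- x / 1000
  y_m <- y / 1000
  my <- -x_m * fz - fx * h
  mx <- y_m * fz + fy * h
  mz <- if (frac > 0) stats::rnorm(n, 0, frac * 0.002) else numeric(n)

  sensor <- data.frame(t_ms = t * 1000, Fx_N = fx, Fy_N = fy, Fz_N = fz,
                       Mx_Nm = mx, My_Nm = my, Mz_Nm = mz)
  truth <- data.frame(texture = texture, condition = condition,
                      violation = violation,
                      onset_ms = lat * 1000,
                      move_start_ms = t_start * 1000,
                      mu = mu, load_g = load_g,
                      speed_peak_mms = v_peak)
  list(sensor = sensor, truth = truth)
}
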