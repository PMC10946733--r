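#' Pipeline configuration
#'
#' Declarative description of an end-to-end run: either a synthetic
#' study configuration or a directory of recordings, plus every stage
#' parameter. All parameters are validated before any computation.
#'
#' @param study a [study_config()] for synthetic runs, or `NULL` when
#'   reading from `input_dir`
#' @param input_dir directory in the [generate_study()] layout
#' @param out_dir artifact directory, or `NULL` for in-memory results
#' @param filter logical; apply the 1-100 Hz band-pass + notch to the
#'   raw EEG (requires `fs >= 256`)
#' @param fs_downsample analysis rate after epoching, Hz; epochs are
#'   left untouched when already at or below this rate
#' @param artifact_threshold_uV peak-to-peak trial rejection threshold
#' @param epoch_tmin_s,epoch_tmax_s epoch window re movement onset
#' @param bands named list of band edges, Hz
#' @param tf_freqs wavelet frequencies; `NULL` = the bins covering
#'   `bands` (use `1:40` for the full decomposition)
#' @param baseline_ms,crop_ms ERSP windows
#' @param image_hz scalp-time frame rate (`NULL` = EEG analysis rate)
#' @param fwhm_mm_mm_ms smoothing kernel FWHM (x mm, y mm, t ms)
#' @param p_form,k_min,connectivity cluster-forming threshold, minimum
#'   extent (voxels) and neighbourhood (6/18/26)
#' @param covariate_mode,centring see [build_design()]
#' @param covariate_screen logical; run [correlation_screen()] and
#'   honour its exclusions
#' @param gg Greenhouse-Geisser policy for behavioural ANOVAs
#' @return validated list of class `pipeline_config`
#' @export
pipeline_config <- function(study = NULL, input_dir = NULL,
                            out_dir = NULL,
                            filter = TRUE, fs_downsample = 256,
                            artifact_threshold_uV = 500,
                            epoch_tmin_s = -5.5, epoch_tmax_s = 5,
                            bands = list(alpha = c(8, 12),
                                         beta = c(16, 24)),
                            tf_freqs = NULL,
                            baseline_ms = c(-4000, -2000),
                            crop_ms = c(0, 4000),
                            image_hz = 16,
                            fwhm_mm_mm_ms = c(9, 9, 20),
                            p_form = 0.001, k_min = 35,
                            connectivity = 18,
                            covariate_mode = "sum",
                            centring = "grand",
                            covariate_screen = TRUE,
                            gg = "auto") {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  chk <- function(ok, msg, ...) if (!ok) stop_atersp("config", msg, ...)
  chk(!is.null(cfg$study) || !is.null(cfg$input_dir),
      "either a synthetic study config or an input_dir is required")
  if (!is.null(cfg$study)) validate_study_config(cfg$study)
  chk(cfg$p_form > 0 && cfg$p_form < 1,
      "p_form = %g outside (0, 1)", cfg$p_form)
  chk(cfg$k_min >= 1, "k_min must be >= 1")
  chk(cfg$connectivity %in% c(6, 18, 26), "connectivity must be 6/18/26")
  chk(all(cfg$fwhm_mm_mm_ms > 0), "FWHM values must be > 0")
  chk(length(cfg$bands) >= 1 && !is.null(names(cfg$bands)),
      "bands must be a named list")
  chk(cfg$epoch_tmin_s < cfg$epoch_tmax_s, "empty epoch window")
  chk(cfg$baseline_ms[1] < cfg$baseline_ms[2], "empty baseline window")
  chk(is.null(cfg$image_hz) || cfg$image_hz > 0, "image_hz must be > 0")
  chk(cfg$fs_downsample > 0, "fs_downsample must be > 0")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Round-trippable YAML serialisation of [pipeline_config()]; the
#' `study` block, when present, is passed to [study_config()].
#'
#' @param path YAML file
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$study)) {
    if (!is.null(y$study$erd_db)) y$study$erd_db <- as.data.frame(y$study$erd_db)
    for (nm in c("mu_friction", "load_condition_shift_g"))
      if (!is.null(y$study[[nm]])) y$study[[nm]] <- unlist(y$study[[nm]])
    if (!is.null(y$study$ratings_mean))
      y$study$ratings_mean <- lapply(y$study$ratings_mean, unlist)
    y$study <- do.call(study_config, y$study)
  }
  for (nm in c("bands"))
    if (!is.null(y[[nm]])) y[[nm]] <- lapply(y[[nm]], unlist)
  for (nm in c("baseline_ms", "crop_ms", "fwhm_mm_mm_ms", "tf_freqs"))
    if (!is.null(y[[nm]])) y[[nm]] <- unlist(y[[nm]])
  do.call(pipeline_config, y)
}

read_subject_dir <- function(input_dir, s, montage, fs_eeg, fs_sensor) {
  tag <- sprintf("sub-%02d", s)
  f <- function(suffix) file.path(input_dir, paste0(tag, suffix))
  ratings_path <- f("_ratings.tsv")
  list(subject = s, montage = montage,
       sensor = read_tsv(f("_sensor.tsv")),
       events = read_tsv(f("_events.tsv")),
       ratings = if (file.exists(ratings_path)) read_tsv(ratings_path),
       eeg = t(as.matrix(read_tsv(f("_eeg.tsv"))[, montage$label])),
       fs_eeg = fs_eeg, fs_sensor = fs_sensor)
}

# One subject: epochs -> band maps -> smoothed scalp-time images ->
# first-level contrasts and per-cell mean images. `tt` is the
# subject's already-computed touch-trial table.
process_subject <- function(sub, pcfg, grid, tt, covariate_plan = NULL) {
  rec <- eeg_recording(sub$eeg, sub$fs_eeg, sub$montage)
  if (isTRUE(pcfg$filter)) rec <- filter_raw(rec)
  ep <- epoch_to_onsets(rec, tt, sub$events,
                        tmin = pcfg$epoch_tmin_s, tmax = pcfg$epoch_tmax_s)
  n_epoch_dropped <- length(ep$dropped)
  if (ep$fs > pcfg$fs_downsample)
    ep <- downsample_epochs(ep, pcfg$fs_downsample)
  ep <- common_average_reference(ep)
  ep <- amplitude_artifact_reject(ep, pcfg$artifact_threshold_uV)
  n_artifact <- attr(ep, "n_rejected") %||% 0

  maps <- band_maps(ep, bands = pcfg$bands, freqs = pcfg$tf_freqs,
                    baseline = pcfg$baseline_ms, crop = pcfg$crop_ms)

  covariates <- TRUE
  covariate_mode <- pcfg$covariate_mode
  if (!is.null(covariate_plan) &&
      !all(c("friction", "load") %in% covariate_plan$combine))
    covariates <- length(covariate_plan$combine) > 0
  design <- build_design(ep$labels, covariate_mode = covariate_mode,
                         centring = pcfg$centring,
                         covariates = covariates)
  contrasts <- paper_contrasts(design)

  cells <- cell_label(ep$labels$texture, ep$labels$condition)
  out <- list(subject = sub$subject, touch = tt,
              n_epoch_dropped = n_epoch_dropped,
              n_artifact = n_artifact, bands = list())
  img_t <- NULL
  for (b in names(maps)) {
    bp <- maps[[b]]
    n_tr <- dim(bp$data)[1]
    sti <- scalp_time_images_smoothed(bp, grid, image_hz = pcfg$image_hz,
                                      fwhm = pcfg$fwhm_mm_mm_ms)
    img_t <- sti$t_ms
    vshape <- sti$vshape
    M <- sti$M
    imgs <- array(M, c(n_tr, vshape))
    con <- fit_first_level(imgs, design, contrasts)
    cellmeans <- lapply(stats::setNames(CELL_LEVELS, CELL_LEVELS),
                        function(cl) {
      rows <- which(cells == cl)
      array(colMeans(M[rows, , drop = FALSE]), vshape)
    })
    out$bands[[b]] <- list(contrasts = con, cellmeans = cellmeans)
  }
  out$image_t_ms <- img_t
  out$labels <- ep$labels
  out
}

cells_of_texture <- list(hessian = c("HH", "SH", "NH"),
                         silk = c("HS", "SS", "NS"))
cells_of_condition <- list(sensory = c("SH", "SS"),
                           hedonic = c("HH", "HS"),
                           none = c("NH", "NS"))

mean_images <- function(cellmeans, cells) {
  a <- simplify2array(cellmeans[cells])
  d <- dim(a)
  vshape <- d[-length(d)]
  array(rowMeans(matrix(a, prod(vshape), d[length(d)])), vshape)
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order, per subject: synthetic generation
#' (or reading from disk), touch kinetics with QC and z-score
#' exclusion, EEG filtering, onset-locked epoching, downsampling,
#' common average reference, artifact rejection, Morlet band ERSP,
#' smoothed scalp-time images, first-level GLM; then at the group
#' level: behavioural ANOVAs and the covariate screen, second-level F
#' maps per band and effect (texture: one-sample; estimation and
#' interaction: joint two-contrast F), cluster-extent thresholding,
#' cluster power extraction and post-hoc tests. When `out_dir` is set
#' the standard artifact files are written
#' (`touch_trials.tsv`, `qc_report.tsv`, `anova_results.tsv`,
#' `posthoc.tsv`, `covariate_plan.json`, `clusters.tsv`,
#' `cluster_power.tsv`, `provenance.json`).
#'
#' @param pcfg a [pipeline_config()]
#' @param progress print per-subject progress
#' @return list of class `pipeline_result`: `clusters` (data.frame),
#'   `cluster_power`, `cluster_tests`, `behaviour` (ANOVA + post-hoc
#'   tables), `covariate_plan`, `qc`, `touch_trials`, `config_echo`
#' @export
run_pipeline <- function(pcfg, progress = FALSE) {
  validate_pipeline_config(pcfg)
  synthetic <- !is.null(pcfg$study)
  if (synthetic) {
    scfg <- pcfg$study
    montage <- make_montage(scfg$n_channels)
    n_sub <- scfg$n_subjects
    fs_sensor <- scfg$fs_sensor
    pre_s <- scfg$baseline_s + scfg$cue_s
    explore_s <- scfg$explore_s
    plate_h <- scfg$plate_h_m
    groups <- channel_groups(montage)
  } else {
    montage <- read_montage_tsv(file.path(pcfg$input_dir, "montage.tsv"))
    meta <- jsonlite::read_json(file.path(pcfg$input_dir, "study.json"))
    n_sub <- meta$n_subjects
    fs_sensor <- meta$fs_sensor
    fs_eeg <- meta$fs_eeg
    pre_s <- 5
    explore_s <- 4
    plate_h <- meta$plate_h_m %||% 0.003
    groups <- NULL
  }
  grid <- scalp_grid(montage)

  # pass 1: touch kinetics and QC for every subject (sensor only),
  # so the covariate screen can inform the first-level designs
  touch_list <- vector("list", n_sub)
  ratings_all <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    if (synthetic) {
      sub0 <- simulate_subject(scfg, s, montage = montage,
                               groups = groups, eeg = FALSE)
      sensor <- sub0$sensor
      events <- sub0$events
      ratings_all[[s]] <- sub0$ratings
    } else {
      tag <- sprintf("sub-%02d", s)
      sensor <- read_tsv(file.path(pcfg$input_dir,
                                   paste0(tag, "_sensor.tsv")))
      events <- read_tsv(file.path(pcfg$input_dir,
                                   paste0(tag, "_events.tsv")))
      rp <- file.path(pcfg$input_dir, paste0(tag, "_ratings.tsv"))
      if (file.exists(rp)) ratings_all[[s]] <- read_tsv(rp)
    }
    touch_list[[s]] <- process_sensor(sensor, events, fs_sensor,
                                      pre_s = pre_s,
                                      explore_s = explore_s,
                                      subject = s, plate_h_m = plate_h)
  }
  touch_all <- do.call(rbind, touch_list)
  ratings <- do.call(rbind, ratings_all)
  plan <- if (pcfg$covariate_screen) correlation_screen(touch_all)

  # pass 2: EEG chain and first-level GLM, one subject in memory at
  # a time
  subjects <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    sub <- if (synthetic) {
      simulate_subject(scfg, s, montage = montage, groups = groups)
    } else {
      read_subject_dir(pcfg$input_dir, s, montage, fs_eeg, fs_sensor)
    }
    subjects[[s]] <- process_subject(sub, pcfg, grid, touch_list[[s]],
                                     covariate_plan = plan)
    rm(sub)
    if (progress)
      message(sprintf("subject %d/%d: %d accepted trials", s, n_sub,
                      sum(subjects[[s]]$touch$accepted)))
  }

  # behavioural statistics
  behaviour <- list(anova = list(), posthoc = list())
  if (!is.null(ratings)) {
    ratings$block <- factor(ratings$block)
    for (sc in unique(ratings$scale)) {
      rsub <- ratings[ratings$scale == sc, ]
      agg <- stats::aggregate(value ~ subject + block + texture, rsub, mean)
      an <- rm_anova(agg, "value", within = c("texture", "block"),
                     gg = pcfg$gg)
      an <- cbind(table = paste0("ratings_", sc), an)
      behaviour$anova[[length(behaviour$anova) + 1]] <- an
      ph <- posthoc_pairwise(agg, "value", "texture")
      behaviour$posthoc[[length(behaviour$posthoc) + 1]] <-
        cbind(table = paste0("ratings_", sc), effect = "texture", ph)
    }
  }
  acc <- touch_all[touch_all$accepted, ]
  for (m in c(speed = "median_speed_mms", friction = "median_friction_n",
              load = "median_load_g")) {
    nm <- names(which(c(speed = "median_speed_mms",
                        friction = "median_friction_n",
                        load = "median_load_g") == m))
    trim <- outlier_trim(acc, m, c("subject", "texture", "condition"))
    an <- rm_anova(trim, m, within = c("texture", "condition"),
                   gg = pcfg$gg)
    behaviour$anova[[length(behaviour$anova) + 1]] <-
      cbind(table = paste0("touch_", nm), an)
    behaviour$posthoc[[length(behaviour$posthoc) + 1]] <-
      cbind(table = paste0("touch_", nm), effect = "condition",
            posthoc_pairwise(trim, m, "condition"))
  }
  behaviour$anova <- do.call(rbind, behaviour$anova)
  behaviour$posthoc <- do.call(rbind, behaviour$posthoc)

  # group-level mass-univariate statistics
  img_t <- subjects[[1]]$image_t_ms
  cluster_rows <- list()
  power_rows <- list()
  test_rows <- list()
  effects <- list(
    texture = list(design = "one_sample", cons = "texture"),
    estimation = list(design = "paired_two_contrast",
                      cons = c("est_sens_vs_hed", "est_hed_vs_none")),
    interaction = list(design = "paired_two_contrast",
                       cons = c("inter_1", "inter_2")))
  for (b in names(pcfg$bands)) {
    for (en in names(effects)) {
      ef <- effects[[en]]
      if (ef$design == "one_sample") {
        imgs <- lapply(subjects, function(s)
          s$bands[[b]]$contrasts[[ef$cons]])
        sl <- second_level_F(imgs, "one_sample")
      } else {
        imgs <- lapply(ef$cons, function(cn)
          lapply(subjects, function(s) s$bands[[b]]$contrasts[[cn]]))
        sl <- second_level_F(imgs, "paired_two_contrast")
      }
      cl <- cluster_threshold(sl$F, sl$df, t_ms = img_t,
                              p_form = pcfg$p_form, k_min = pcfg$k_min,
                              connectivity = pcfg$connectivity)
      for (c1 in cl) {
        cluster_rows[[length(cluster_rows) + 1]] <- data.frame(
          band = b, effect = en, cluster = c1$id, k = c1$k,
          peak_F = c1$peak_F, df1 = sl$df[1], df2 = sl$df[2],
          f_threshold = attr(cl, "threshold"),
          peak_x_mm = grid$px_x[c1$peak_xyz[1]],
          peak_y_mm = grid$px_y[c1$peak_xyz[2]],
          peak_latency_ms = c1$peak_latency_ms)
      }
      if (length(cl)) {
        cond_cells <- switch(en,
          texture = cells_of_texture,
          estimation = cells_of_condition,
          interaction = stats::setNames(as.list(CELL_LEVELS), CELL_LEVELS))
        imgs_sc <- lapply(subjects, function(s)
          lapply(cond_cells, function(cc)
            mean_images(s$bands[[b]]$cellmeans, cc)))
        pw <- extract_cluster_power(cl, imgs_sc)
        pw <- cbind(band = b, effect = en, pw)
        power_rows[[length(power_rows) + 1]] <- pw
        for (c1 in cl) {
          pc <- pw[pw$cluster == c1$id, ]
          tst <- switch(en,
            texture = {
              ph <- posthoc_pairwise(pc, "mean_db", "condition")
              data.frame(test = "paired_t", statistic = ph$t[1],
                         df = ph$df[1], p = ph$p[1])
            },
            estimation = {
              an <- rm_anova_oneway(pc, "mean_db", "condition",
                                    gg = pcfg$gg)
              data.frame(test = "oneway_rm_anova", statistic = an$F,
                         df = an$df2_corr, p = an$p_reported)
            },
            interaction = {
              pc2 <- pc
              pc2$texture <- ifelse(substr(pc2$condition, 2, 2) == "H",
                                    "hessian", "silk")
              pc2$cond <- c(S = "sensory", H = "hedonic",
                            N = "none")[substr(pc2$condition, 1, 1)]
              an <- rm_anova(pc2, "mean_db",
                             within = c("texture", "cond"), gg = pcfg$gg)
              ia <- an[an$effect == "texture:cond", ]
              data.frame(test = "twoway_rm_anova", statistic = ia$F,
                         df = ia$df2_corr, p = ia$p_reported)
            })
          test_rows[[length(test_rows) + 1]] <-
            cbind(band = b, effect = en, cluster = c1$id, tst)
        }
      }
    }
  }
  clusters <- if (length(cluster_rows)) do.call(rbind, cluster_rows)
    else data.frame(band = character(0), effect = character(0),
                    cluster = integer(0), k = integer(0),
                    peak_F = numeric(0), df1 = numeric(0),
                    df2 = numeric(0), f_threshold = numeric(0),
                    peak_x_mm = numeric(0), peak_y_mm = numeric(0),
                    peak_latency_ms = numeric(0))
  cluster_power <- if (length(power_rows)) do.call(rbind, power_rows)
    else data.frame(band = character(0), effect = character(0),
                    cluster = integer(0), subject = integer(0),
                    condition = character(0), mean_db = numeric(0))
  cluster_tests <- if (length(test_rows)) do.call(rbind, test_rows)

  # QC accounting: trials entering / surviving each rule
  flag_count <- function(tt, fl) sum(grepl(fl, tt$qc_flags, fixed = TRUE))
  qc <- do.call(rbind, lapply(subjects, function(s) {
    tt <- s$touch
    data.frame(subject = s$subject, n_trials = nrow(tt),
               no_trigger = flag_count(tt, "no_trigger"),
               baseline_movement = flag_count(tt, "baseline_movement"),
               late_onset = flag_count(tt, "late_onset"),
               zscore_outlier = flag_count(tt, "zscore_outlier"),
               accepted = sum(tt$accepted),
               epoch_dropped = s$n_epoch_dropped,
               artifact_rejected = s$n_artifact)
  }))

  res <- structure(list(clusters = clusters,
                        cluster_power = cluster_power,
                        cluster_tests = cluster_tests,
                        behaviour = behaviour,
                        covariate_plan = plan, qc = qc,
                        touch_trials = touch_all,
                        image_t_ms = img_t,
                        subjects = subjects, grid = grid),
                   class = "pipeline_result")
  if (!is.null(pcfg$out_dir)) write_artifacts(res, pcfg)
  res
}

write_artifacts <- function(res, pcfg) {
  out <- pcfg$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  write_tsv(res$touch_trials, file.path(out, "touch_trials.tsv"))
  write_tsv(res$qc, file.path(out, "qc_report.tsv"))
  write_tsv(res$behaviour$anova, file.path(out, "anova_results.tsv"))
  write_tsv(res$behaviour$posthoc, file.path(out, "posthoc.tsv"))
  write_tsv(res$clusters, file.path(out, "clusters.tsv"))
  write_tsv(res$cluster_power, file.path(out, "cluster_power.tsv"))
  if (!is.null(res$cluster_tests))
    write_tsv(res$cluster_tests, file.path(out, "cluster_tests.tsv"))
  if (!is.null(res$covariate_plan))
    jsonlite::write_json(
      list(combine = res$covariate_plan$combine,
           exclude = res$covariate_plan$exclude,
           covariate = res$covariate_plan$covariate),
      file.path(out, "covariate_plan.json"), auto_unbox = TRUE)
  prov <- list(
    package_version = as.character(utils::packageVersion("atersp")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = NULL,                      # deliberately omitted: byte-stable
    seed = if (!is.null(pcfg$study)) pcfg$study$seed,
    parameters = list(
      filter = pcfg$filter, fs_downsample = pcfg$fs_downsample,
      artifact_threshold_uV = pcfg$artifact_threshold_uV,
      bands = pcfg$bands, baseline_ms = pcfg$baseline_ms,
      crop_ms = pcfg$crop_ms, image_hz = pcfg$image_hz,
      fwhm = pcfg$fwhm_mm_mm_ms, p_form = pcfg$p_form,
      k_min = pcfg$k_min, connectivity = pcfg$connectivity,
      covariate_mode = pcfg$covariate_mode, centring = pcfg$centring))
  jsonlite::write_json(prov, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

#' Human-readable summary of a completed run
#'
#' Summarises the artifact files of a pipeline run: trials retained
#' per subject and rejection rule, significant clusters per effect and
#' band with extents and peak latencies, and the behavioural post-hoc
#' tables. Every number is read back from the persisted TSVs.
#'
#' @param out_dir artifact directory of a completed [run_pipeline()]
#' @return character vector of report lines (also printed invisibly
#'   usable via `writeLines`)
#' @export
pipeline_report <- function(out_dir) {
  need <- c("qc_report.tsv", "clusters.tsv", "anova_results.tsv")
  missing <- need[!file.exists(file.path(out_dir, need))]
  if (length(missing))
    stop_atersp("io", "missing artifact(s) in '%s': %s", out_dir,
                paste(missing, collapse = ", "))
  qc <- read_tsv(file.path(out_dir, "qc_report.tsv"))
  cl <- read_tsv(file.path(out_dir, "clusters.tsv"))
  an <- read_tsv(file.path(out_dir, "anova_results.tsv"))
  lines <- c("# Active-touch ERSP pipeline report", "",
             "## Trial quality control", "")
  lines <- c(lines, sprintf(
    "- subject %d: %d/%d accepted (no_trigger %d, baseline_movement %d, late_onset %d, zscore %d, artifact %d)",
    qc$subject, qc$accepted, qc$n_trials, qc$no_trigger,
    qc$baseline_movement, qc$late_onset, qc$zscore_outlier,
    qc$artifact_rejected))
  lines <- c(lines, "", "## Significant clusters", "")
  if (!nrow(cl)) {
    lines <- c(lines, "- no clusters survived in any band or effect")
  } else {
    lines <- c(lines, sprintf(
      "- %s / %s: cluster %d, k = %d, peak F = %.2f (df %g, %g), peak latency %.0f ms",
      cl$band, cl$effect, cl$cluster, cl$k, cl$peak_F, cl$df1, cl$df2,
      cl$peak_latency_ms))
  }
  lines <- c(lines, "", "## Behavioural ANOVAs", "")
  lines <- c(lines, sprintf(
    "- %s, %s: F(%.2f, %.2f) = %.2f, p = %.4g, pes = %.3f",
    an$table, an$effect, an$df1_corr, an$df2_corr, an$F,
    an$p_reported, an$pes))
  lines
}
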