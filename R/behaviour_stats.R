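# Orthonormal contrast matrix for a k-level within factor (k x (k-1)).
orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

# Greenhouse-Geisser epsilon and Mauchly's sphericity test from an
# n x p matrix of orthonormal-contrast-transformed subject scores.
sphericity_stats <- function(Z) {
  p <- ncol(Z)
  n <- nrow(Z)
  if (p < 2) return(list(epsilon = 1, mauchly_W = NA_real_,
                         mauchly_p = NA_real_))
  S <- stats::cov(Z)
  eps <- sum(diag(S))^2 / (p * sum(S^2))
  detS <- det(S)
  if (!is.finite(detS) || detS <= 0 || n - 1 <= p)
    return(list(epsilon = eps, mauchly_W = NA_real_,
                mauchly_p = NA_real_))
  W <- detS / (sum(diag(S)) / p)^p
  dfc <- p * (p + 1) / 2 - 1
  f <- 1 - (2 * p^2 + p + 2) / (6 * p * (n - 1))
  chi <- -f * (n - 1) * log(W)
  list(epsilon = eps, mauchly_W = W,
       mauchly_p = stats::pchisq(chi, dfc, lower.tail = FALSE))
}

#' Two-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fully within-subject two-factor ANOVA on a balanced long table
#' (values are aggregated to subject x cell means first). Sums of
#' squares and F statistics come from [stats::aov()] with the
#' appropriate error strata; partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`. The Greenhouse-Geisser
#' epsilon is computed from the covariance of the orthonormal contrast
#' scores of each effect (interaction: Kronecker product of the factor
#' contrasts) and is reported for every effect; the corrected p-value
#' replaces the uncorrected one when the effect has more than one
#' numerator df and Mauchly's test rejects sphericity
#' (`gg = "auto"`), always (`"always"`), or never (`"never"`).
#' For two-level factors epsilon is exactly 1.
#'
#' @param data long data.frame
#' @param dv,subject column names of the value and subject id
#' @param within length-2 character vector of within-subject factors
#' @param gg Greenhouse-Geisser policy
#' @param mauchly_alpha sphericity-test level for `gg = "auto"`; a
#'   non-computable test (too few subjects) is treated as a violation
#' @return data.frame of class `rm_anova`: one row per effect with
#'   `F`, `df1`, `df2`, `p`, `pes`, `epsilon`, `mauchly_p`,
#'   `df1_corr`, `df2_corr`, `p_reported`, `gg_applied`
#' @export
rm_anova <- function(data, dv, within, subject = "subject",
                     gg = c("auto", "always", "never"),
                     mauchly_alpha = 0.05) {
  gg <- match.arg(gg)
  if (length(within) != 2)
    stop_atersp("input", "rm_anova expects exactly two within factors")
  d <- data.frame(y = data[[dv]],
                  s = factor(data[[subject]]),
                  A = factor(data[[within[1]]]),
                  B = factor(data[[within[2]]]))
  if (anyNA(d)) stop_atersp("input", "missing values in ANOVA input")
  agg <- stats::aggregate(y ~ s + A + B, d, mean)
  tab <- table(agg$s, agg$A, agg$B)
  if (any(tab != 1)) {
    miss <- which(tab == 0, arr.ind = TRUE)
    stop_atersp("input", "unbalanced design; %d empty subject cells (e.g. %s)",
                nrow(miss), paste(dimnames(tab)[[2]][miss[1, 2]],
                                  dimnames(tab)[[3]][miss[1, 3]]))
  }
  n <- nlevels(agg$s)
  if (n < 3) stop_atersp("input", "need >= 3 subjects")
  a <- nlevels(agg$A)
  b <- nlevels(agg$B)

  fit <- stats::aov(y ~ A * B + Error(s / (A * B)), data = agg)
  sm <- summary(fit)
  pull <- function(stratum, effect) {
    tb <- sm[[stratum]][[1]]
    i <- match(effect, trimws(rownames(tb)))
    e <- match("Residuals", trimws(rownames(tb)))
    list(ss = tb[i, "Sum Sq"], sse = tb[e, "Sum Sq"],
         df1 = tb[i, "Df"], df2 = tb[e, "Df"],
         F = tb[i, "F value"], p = tb[i, "Pr(>F)"])
  }
  eff <- list(
    A = pull("Error: s:A", "A"),
    B = pull("Error: s:B", "B"),
    `A:B` = pull("Error: s:A:B", "A:B"))

  # subject x cell matrix in (B within A) column order
  wide <- matrix(agg$y[order(agg$A, agg$B, agg$s)], nrow = n)
  CA <- orthonormal_contrasts(a)
  CB <- orthonormal_contrasts(b)
  one_a <- rep(1 / sqrt(a), a)
  one_b <- rep(1 / sqrt(b), b)
  Tmats <- list(A = kronecker(CA, one_b), B = kronecker(one_a, CB),
                `A:B` = kronecker(CA, CB))

  rows <- lapply(names(eff), function(nm) {
    e <- eff[[nm]]
    sp <- sphericity_stats(wide %*% Tmats[[nm]])
    apply_gg <- switch(gg,
      never = FALSE,
      always = e$df1 > 1,
      auto = e$df1 > 1 && (is.na(sp$mauchly_p) ||
                             sp$mauchly_p < mauchly_alpha))
    d1c <- if (apply_gg) e$df1 * sp$epsilon else e$df1
    d2c <- if (apply_gg) e$df2 * sp$epsilon else e$df2
    data.frame(effect = gsub("A", within[1], gsub("B", within[2], nm)),
               F = e$F, df1 = e$df1, df2 = e$df2, p = e$p,
               pes = e$ss / (e$ss + e$sse),
               epsilon = sp$epsilon, mauchly_p = sp$mauchly_p,
               df1_corr = d1c, df2_corr = d2c,
               p_reported = stats::pf(e$F, d1c, d2c, lower.tail = FALSE),
               gg_applied = apply_gg)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rm_anova", class(out))
  attr(out, "n_subjects") <- n
  out
}

#' One-way repeated-measures ANOVA
#'
#' Single within-subject factor companion to [rm_anova()], used for
#' post-hoc tests on extracted cluster power; same Greenhouse-Geisser
#' conventions.
#'
#' @inheritParams rm_anova
#' @param within single within-subject factor name
#' @return one-row data.frame with the same columns as [rm_anova()]
#' @export
rm_anova_oneway <- function(data, dv, within, subject = "subject",
                            gg = c("auto", "always", "never"),
                            mauchly_alpha = 0.05) {
  gg <- match.arg(gg)
  d <- data.frame(y = data[[dv]], s = factor(data[[subject]]),
                  A = factor(data[[within[1]]]))
  agg <- stats::aggregate(y ~ s + A, d, mean)
  n <- nlevels(agg$s)
  a <- nlevels(agg$A)
  if (n < 3) stop_atersp("input", "need >= 3 subjects")
  if (any(table(agg$s, agg$A) != 1))
    stop_atersp("input", "unbalanced one-way design")
  fit <- stats::aov(y ~ A + Error(s / A), data = agg)
  tb <- summary(fit)[["Error: s:A"]][[1]]
  ia <- match("A", trimws(rownames(tb)))
  ie <- match("Residuals", trimws(rownames(tb)))
  ss <- tb[ia, "Sum Sq"]
  sse <- tb[ie, "Sum Sq"]
  Fv <- tb[ia, "F value"]
  wide <- matrix(agg$y[order(agg$A, agg$s)], nrow = n)
  sp <- sphericity_stats(wide %*% orthonormal_contrasts(a))
  apply_gg <- switch(gg, never = FALSE, always = a > 2,
                     auto = a > 2 && (is.na(sp$mauchly_p) ||
                                        sp$mauchly_p < mauchly_alpha))
  d1 <- a - 1
  d2 <- (a - 1) * (n - 1)
  d1c <- if (apply_gg) d1 * sp$epsilon else d1
  d2c <- if (apply_gg) d2 * sp$epsilon else d2
  out <- data.frame(effect = within[1], F = Fv, df1 = d1, df2 = d2,
                    p = tb[ia, "Pr(>F)"], pes = ss / (ss + sse),
                    epsilon = sp$epsilon, mauchly_p = sp$mauchly_p,
                    df1_corr = d1c, df2_corr = d2c,
                    p_reported = stats::pf(Fv, d1c, d2c,
                                           lower.tail = FALSE),
                    gg_applied = apply_gg)
  class(out) <- c("rm_anova", class(out))
  out
}

#' Bonferroni-adjusted pairwise post-hoc comparisons
#'
#' Paired t-tests on subject-level means for every level pair of one
#' within-subject factor; adjusted p = min(1, p * m) over the m pairs.
#'
#' @param data long data.frame
#' @param dv,subject,factor column names
#' @return data.frame: `level_1`, `level_2`, `mean_diff`, `t`, `df`,
#'   `p`, `p_adj`
#' @export
posthoc_pairwise <- function(data, dv, factor, subject = "subject") {
  d <- data.frame(y = data[[dv]], s = factor(data[[subject]]),
                  f = factor(data[[factor]]))
  agg <- stats::aggregate(y ~ s + f, d, mean)
  levs <- levels(agg$f)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  rows <- lapply(pairs, function(p) {
    y1 <- agg$y[agg$f == p[1]][order(agg$s[agg$f == p[1]])]
    y2 <- agg$y[agg$f == p[2]][order(agg$s[agg$f == p[2]])]
    dif <- y1 - y2
    if (stats::sd(dif) == 0) {
      # degenerate: no within-pair variability
      return(data.frame(level_1 = p[1], level_2 = p[2],
                        mean_diff = mean(dif),
                        t = if (mean(dif) == 0) 0 else Inf * sign(mean(dif)),
                        df = length(dif) - 1,
                        p = as.numeric(mean(dif) == 0)))
    }
    tt <- stats::t.test(y1, y2, paired = TRUE)
    data.frame(level_1 = p[1], level_2 = p[2],
               mean_diff = mean(dif),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p * nrow(out))
  out
}

#' Remove statistical outliers (|z| > 2) within groups
#'
#' Single-pass removal of values whose within-group z-score strictly
#' exceeds the criterion (sample SD); groups with fewer than 3 values
#' or zero SD pass through unchanged.
#'
#' @param data data.frame
#' @param value column to screen
#' @param group_cols grouping columns
#' @param z_max criterion (strict)
#' @return filtered data.frame; attribute `n_removed`
#' @export
outlier_trim <- function(data, value, group_cols, z_max = 2) {
  key <- interaction(data[group_cols], drop = TRUE)
  keep <- rep(TRUE, nrow(data))
  for (g in levels(key)) {
    i <- which(key == g)
    if (length(i) < 3) next
    v <- data[[value]][i]
    s <- stats::sd(v)
    if (!is.finite(s) || s <= 1e-10 * max(abs(v), 1)) next
    keep[i] <- abs((v - mean(v)) / s) <= z_max
  }
  out <- data[keep, ]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Correlation screen deciding the GLM covariate plan
#'
#' Applies the regressor-selection rules to per-subject touch
#' behaviour: (1) behaviour pairs whose subject-level means are
#' significantly Pearson-correlated (p < alpha) in *both* textures are
#' combined by summation into a single regressor; (2) behaviours whose
#' repeated-measures ANOVA (2 textures x 3 estimation conditions)
#' shows no significant texture or estimation effect are excluded from
#' the design altogether.
#'
#' @param touch_trials accepted touch-trial table (all subjects)
#' @param alpha significance level for both rules
#' @return list of class `covariate_plan`: `correlations` (per texture
#'   and pair: r, p), `anova_p` (per measure: texture / estimation
#'   p-values), `combine` (character vector of combined measures),
#'   `exclude`, `covariate` (label of the regressor to enter)
#' @export
correlation_screen <- function(touch_trials, alpha = 0.05) {
  tt <- touch_trials[touch_trials$accepted, ]
  if (length(unique(tt$subject)) < 3)
    stop_atersp("input", "correlation screen needs >= 3 subjects")
  measures <- c(speed = "median_speed_mms", friction = "median_friction_n",
                load = "median_load_g")

  # subject x texture means for correlations
  cors <- list()
  pairs <- utils::combn(names(measures), 2, simplify = FALSE)
  for (tx in TEXTURES) {
    sub <- tt[tt$texture == tx, ]
    agg <- stats::aggregate(sub[unname(measures)],
                            by = list(subject = sub$subject), mean)
    for (p in pairs) {
      ct <- stats::cor.test(agg[[measures[p[1]]]], agg[[measures[p[2]]]])
      cors[[length(cors) + 1]] <- data.frame(
        texture = tx, var_1 = p[1], var_2 = p[2],
        r = unname(ct$estimate), p = ct$p.value)
    }
  }
  cors <- do.call(rbind, cors)

  # effect screen: 2 x 3 rm-ANOVA per measure
  anova_p <- lapply(measures, function(m) {
    an <- rm_anova(tt, dv = m, within = c("texture", "condition"))
    c(texture = an$p_reported[an$effect == "texture"],
      estimation = an$p_reported[an$effect == "condition"])
  })
  has_effect <- vapply(anova_p, function(p) any(p < alpha), logical(1))
  exclude <- names(measures)[!has_effect]

  combine <- character(0)
  for (p in pairs) {
    hit <- cors$var_1 == p[1] & cors$var_2 == p[2] & cors$p < alpha
    both_eff <- all(c(p[1], p[2]) %in% names(measures)[has_effect])
    if (sum(hit) == length(TEXTURES) && both_eff) combine <- union(combine, p)
  }
  covariate <- if (length(combine)) paste(combine, collapse = "+")
               else paste(setdiff(names(measures)[has_effect], exclude),
                          collapse = ",")
  structure(list(correlations = cors,
                 anova_p = do.call(rbind, anova_p),
                 combine = combine, exclude = exclude,
                 covariate = covariate),
            class = "covariate_plan")
}
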