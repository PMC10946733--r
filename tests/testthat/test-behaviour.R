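toy_2x2 <- function(n = 5, seed = 1, effect_a = 0.8) {
  set.seed(seed)
  d <- expand.grid(subject = seq_len(n), A = c("a1", "a2"),
                   B = c("b1", "b2", "b3"))
  d$y <- rnorm(nrow(d)) + effect_a * (d$A == "a2") +
    rep(rnorm(n), length.out = nrow(d))
  d
}

test_that("rm-ANOVA matches a brute-force sums-of-squares oracle", {
  d <- toy_2x2()
  an <- rm_anova(d, "y", within = c("A", "B"))
  # independent cell-means oracle
  n <- 5; a <- 2; b <- 3
  cell <- with(d, tapply(y, list(subject, A, B), mean))
  ym <- mean(cell)
  subj <- apply(cell, 1, mean)
  Am <- apply(cell, 2, mean); Bm <- apply(cell, 3, mean)
  AB <- apply(cell, c(2, 3), mean)
  sA <- apply(cell, c(1, 2), mean); sB <- apply(cell, c(1, 3), mean)
  ssA <- n * b * sum((Am - ym)^2)
  ssB <- n * a * sum((Bm - ym)^2)
  ssAB <- n * sum((sweep(sweep(AB, 1, Am), 2, Bm) + ym)^2)
  ssAs <- b * sum((sA - outer(subj, rep(1, a)) -
                     outer(rep(1, n), Am) + ym)^2)
  ssBs <- a * sum((sB - outer(subj, rep(1, b)) -
                     outer(rep(1, n), Bm) + ym)^2)
  resid <- cell
  for (i in 1:n) for (j in 1:a) for (k in 1:b)
    resid[i, j, k] <- cell[i, j, k] - sA[i, j] - sB[i, k] - AB[j, k] +
      subj[i] + Am[j] + Bm[k] - ym
  ssABs <- sum(resid^2)
  FA <- (ssA / (a - 1)) / (ssAs / ((a - 1) * (n - 1)))
  FB <- (ssB / (b - 1)) / (ssBs / ((b - 1) * (n - 1)))
  FAB <- (ssAB / ((a - 1) * (b - 1))) /
    (ssABs / ((a - 1) * (b - 1) * (n - 1)))
  expect_equal(an$F, c(FA, FB, FAB), tolerance = 1e-9)
  expect_equal(an$df1, c(1, 2, 2))
  expect_equal(an$df2, c(4, 8, 8))
  expect_equal(an$pes, c(ssA / (ssA + ssAs), ssB / (ssB + ssBs),
                         ssAB / (ssAB + ssABs)), tolerance = 1e-9)
  # decomposition: total SS = subjects + effects + errors
  sstot <- sum((cell - ym)^2)
  expect_equal(sstot, a * b * sum((subj - ym)^2) + ssA + ssB + ssAB +
                 ssAs + ssBs + ssABs, tolerance = 1e-9)
})

test_that("Greenhouse-Geisser epsilon is 1 for 2-level factors and
           near 1 for compound-symmetric data", {
  d <- toy_2x2()
  an <- rm_anova(d, "y", within = c("A", "B"))
  expect_equal(an$epsilon[an$effect == "A"], 1)
  # compound symmetry at large n: epsilon approaches 1
  set.seed(12)
  n <- 200
  cs <- expand.grid(subject = seq_len(n), A = c("x", "y"),
                    B = c("b1", "b2", "b3", "b4"))
  cs$y <- rnorm(nrow(cs)) + rep(rnorm(n, sd = 2), length.out = nrow(cs))
  an2 <- rm_anova(cs, "y", within = c("A", "B"))
  expect_lt(abs(an2$epsilon[an2$effect == "B"] - 1), 0.05)
  # bounds respected on arbitrary random data
  for (seed in 1:5) {
    dd <- toy_2x2(n = 6, seed = seed)
    aa <- rm_anova(dd, "y", within = c("A", "B"))
    k <- c(2, 3, 6)
    lower <- 1 / (c(1, 2, 2))
    expect_true(all(aa$epsilon <= 1 + 1e-12))
    expect_true(all(aa$epsilon >= 1 / pmax(aa$df1, 1) - 1e-12))
  }
  expect_error(rm_anova(toy_2x2(n = 2), "y", within = c("A", "B")),
               class = "atersp_input_error")
})

test_that("post-hoc comparisons use Bonferroni min(1, p*m)", {
  d <- toy_2x2(n = 6, seed = 4, effect_a = 0)
  ph <- posthoc_pairwise(d, "y", "B")
  expect_equal(nrow(ph), 3)
  expect_equal(ph$p_adj, pmin(1, ph$p * 3))
  expect_true(all(ph$p_adj >= ph$p))

  # identical level values: degenerate differences give p = 1
  d2 <- d
  d2$y <- rep(rnorm(6), length.out = nrow(d2))
  ph2 <- posthoc_pairwise(d2, "y", "B")
  expect_true(all(ph2$p_adj == 1))

  # closed-form paired t on a 4-subject toy table
  d3 <- data.frame(subject = rep(1:4, 2),
                   f = rep(c("u", "v"), each = 4),
                   y = c(1, 2, 3, 4, 2, 2.5, 4.5, 4))
  ph3 <- posthoc_pairwise(d3, "y", "f")
  dif <- c(1, 2, 3, 4) - c(2, 2.5, 4.5, 4)
  t_hand <- mean(dif) / (sd(dif) / 2)
  expect_equal(ph3$t, t_hand, tolerance = 1e-12)
  expect_equal(ph3$df, 3)
})

test_that("outlier trimming is strict +/- 2 SD within groups", {
  g <- data.frame(grp = "a", v = c(rep(10, 9), 20))
  tr <- outlier_trim(g, "v", "grp")
  expect_equal(nrow(tr), 9)          # |z| = 2.846 removed
  g2 <- data.frame(grp = "a", v = rep(5, 8))
  expect_equal(nrow(outlier_trim(g2, "v", "grp")), 8)
  g3 <- data.frame(grp = "a", v = c(-1, rep(0, 7), 1))  # max |z| = 2
  expect_equal(nrow(outlier_trim(g3, "v", "grp")), 9)
})

test_that("correlation screen combines coupled and drops inert measures", {
  set.seed(6)
  subs <- 6
  tt <- expand.grid(trial = 1:4, subject = 1:subs,
                    texture = c("hessian", "silk"),
                    condition = c("sensory", "hedonic", "none"),
                    stringsAsFactors = FALSE)
  tt$block <- 1
  load <- 150 + 20 * as.numeric(scale(tt$subject)) + rnorm(nrow(tt), 0, 5)
  tt$median_load_g <- load + 10 * (tt$condition == "hedonic")
  tt$median_friction_n <- 2 * tt$median_load_g / 1000 +
    0.5 * (tt$texture == "hessian")
  tt$median_speed_mms <- rnorm(nrow(tt), 150, 10)   # condition-free
  tt$onset_ms <- 250
  tt$qc_flags <- ""
  tt$accepted <- TRUE
  plan <- correlation_screen(tt)
  expect_setequal(plan$combine, c("friction", "load"))
  expect_equal(plan$exclude, "speed")
  expect_equal(plan$covariate, "friction+load")
  r <- plan$correlations
  expect_true(all(r$r[r$var_1 == "friction" & r$var_2 == "load"] > 0.9))
  expect_error(correlation_screen(tt[tt$subject == 1, ]),
               class = "atersp_input_error")
})

test_that("one-way rm-ANOVA agrees with aov and handles GG", {
  set.seed(3)
  d <- expand.grid(subject = 1:8, g = c("p", "q", "r"))
  d$y <- rnorm(nrow(d)) + 0.5 * (d$g == "r")
  an <- rm_anova_oneway(d, "y", "g", gg = "never")
  fit <- summary(aov(y ~ g + Error(factor(subject) / g), d))
  tb <- fit[["Error: factor(subject):g"]][[1]]
  expect_equal(an$F, tb[match("g", trimws(rownames(tb))), "F value"],
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(an$df1, 2)
  expect_equal(an$df2, 14)
  always <- rm_anova_oneway(d, "y", "g", gg = "always")
  expect_true(always$gg_applied)
  expect_lt(always$df1_corr, 2 + 1e-12)
})
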