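test_that("design matrix has one-hot cells and centred covariates", {
  tr <- fake_trials(reps = 1)
  d <- build_design(tr)
  D <- d$X[, 1:6]
  expect_true(all(rowSums(D) == 1))
  expect_equal(unname(sort(colSums(D))), rep(1, 6))  # identity up to order
  # whole-column policy zeroes every covariate column mean
  dcol <- build_design(tr, centring = "column")
  expect_lt(max(abs(colMeans(dcol$X[, 7:12]))), 1e-12)

  tr2 <- fake_trials(reps = 3)
  d2 <- build_design(tr2)
  expect_equal(qr(d2$X)$rank, 12)

  # grand centring keeps covariates nonzero only inside their cell
  dg <- build_design(tr2, centring = "grand")
  for (j in 1:6)
    expect_true(all(dg$X[dg$X[, j] == 0, 6 + j] == 0))

  # cell centring zeroes each cell's covariate mean
  dc <- build_design(tr2, centring = "cell")
  for (j in 1:6)
    expect_lt(abs(sum(dc$X[, 6 + j])), 1e-12)

  tr3 <- tr2[tr2$condition != "hedonic" | tr2$texture != "silk", ]
  expect_error(build_design(tr3), class = "atersp_input_error")
})

test_that("first-level OLS recovers noiseless coefficients exactly", {
  set.seed(3)
  tr <- fake_trials(reps = 4)
  d <- build_design(tr)
  beta_true <- rnorm(12)
  V <- 30
  Y <- d$X %*% matrix(rep(beta_true, V), 12, V)
  con <- fit_first_level(array(Y, c(nrow(Y), V)), d)
  cv <- paper_contrasts(d)$texture
  expect_lt(max(abs(con$texture - sum(cv * beta_true))), 1e-10)

  # voxelwise beta equals an independent lm() solve
  Yn <- Y + rnorm(length(Y))
  con2 <- fit_first_level(array(Yn, c(nrow(Yn), V)), d)
  b_lm <- coef(lm(Yn[, 1] ~ 0 + d$X))
  expect_equal(unname(attr(con2, "beta")[, 1]), unname(b_lm),
               tolerance = 1e-10)

  # shifting the covariate pre-centring leaves contrast images intact
  tr_shift <- tr
  tr_shift$median_load_g <- tr_shift$median_load_g + 500
  d_shift <- build_design(tr_shift)
  c1 <- fit_first_level(array(Yn, c(nrow(Yn), V)), d)
  c2 <- fit_first_level(array(Yn, c(nrow(Yn), V)), d_shift)
  expect_equal(c1$texture, c2$texture, tolerance = 1e-8)

  # rank-deficient designs are refused with the offending column named
  tr_bad <- fake_trials(reps = 2)
  tr_bad$median_friction_n <- 1
  tr_bad$median_load_g <- 150            # constant covariate per cell
  expect_error(build_design(tr_bad) |> fit_first_level(
    images = array(rnorm(12 * 4), c(12, 4)), design = _),
    class = "atersp_numeric_error")
})

test_that("contrast weights encode the five standard effects", {
  d <- build_design(fake_trials(reps = 2))
  cv <- paper_contrasts(d)
  expect_equal(sum(cv$texture), 0)
  expect_equal(cv$texture[["HH"]], 1 / 3)
  expect_equal(cv$texture[["NS"]], -1 / 3)
  expect_equal(cv$est_sens_vs_hed[["SS"]], 1 / 2)
  expect_equal(cv$inter_1[["SH"]], 1 / 2)
  expect_equal(cv$inter_2[["NS"]], 1 / 2)
  for (v in cv) expect_equal(sum(v), 0)
})

test_that("second-level F behaves like t^2 and the explicit GLM", {
  set.seed(8)
  # near-constant images: enormous F; sign-alternating: F ~ 0
  big <- lapply(1:4, function(i) array(1 + rnorm(8, sd = 1e-4), c(2, 2, 2)))
  alt <- lapply(1:4, function(i) array(c(1, -1)[(i %% 2) + 1], c(2, 2, 2)))
  Fb <- second_level_F(big)
  expect_true(all(Fb$F > 1e4))
  Fa <- second_level_F(alt)
  expect_true(all(Fa$F < 1e-10))

  imgs <- lapply(1:6, function(i) array(rnorm(12), c(3, 4)))
  sl <- second_level_F(imgs)
  m <- sapply(imgs, function(a) a[2, 3])
  tt <- t.test(m)
  expect_equal(sl$F[2, 3], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(sl$df, c(1, 5))

  # paired_two_contrast equals the sums-of-squares GLM oracle
  A <- lapply(1:5, function(i) array(rnorm(4), c(2, 2)))
  B <- lapply(1:5, function(i) array(rnorm(4), c(2, 2)))
  sl2 <- second_level_F(list(A, B), "paired_two_contrast")
  ya <- sapply(A, function(a) a[1, 2])
  yb <- sapply(B, function(a) a[1, 2])
  y <- c(ya, yb)
  X <- cbind(rep(c(1, 0), each = 5), rep(c(0, 1), each = 5))
  rss1 <- sum(lm.fit(X, y)$residuals^2)
  Fo <- ((sum(y^2) - rss1) / 2) / (rss1 / 8)
  expect_equal(sl2$F[1, 2], Fo, tolerance = 1e-10)
  expect_equal(sl2$df, c(2, 8))
  expect_error(second_level_F(list(A, B[1:4]), "paired_two_contrast"),
               class = "atersp_input_error")
})

test_that("cluster extraction respects threshold, extent, connectivity", {
  d <- c(10, 10, 10)
  base <- array(0, d)
  df <- c(1, 30)
  thr <- qf(0.999, 1, 30)
  # a 40-voxel supra-threshold box survives; 34 voxels do not
  f40 <- base
  f40[2:5, 2:3, 2:6] <- thr + 5           # 4*2*5 = 40
  cl <- cluster_threshold(f40, df)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$k, 40)
  f34 <- base
  f34[2:5, 2:3, 2:5] <- thr + 5           # 32 < 35
  f34[2:3, 4, 2] <- thr + 5               # 34 total (connected)
  expect_length(cluster_threshold(f34, df), 0)

  # corner-only contact splits under 18-connectivity, joins under 26
  f2 <- base
  f2[1:3, 1:3, 1:2] <- thr + 1
  f2[4:6, 4:6, 3:4] <- thr + 1            # meets previous at a corner
  cl18 <- cluster_threshold(f2, df, k_min = 1)
  expect_length(cl18, 2)
  cl26 <- cluster_threshold(f2, df, k_min = 1, connectivity = 26)
  expect_length(cl26, 1)
  # edge contact joins under 18-connectivity
  f3 <- base
  f3[1:3, 1:3, 1:2] <- thr + 1
  f3[4:6, 3:5, 3:4] <- thr + 1
  expect_length(cluster_threshold(f3, df, k_min = 1), 1)

  # threshold equals the F quantile and falls as df2 grows
  expect_equal(attr(cl, "threshold"), qf(1 - 0.001, 1, 30))
  t1 <- attr(cluster_threshold(base, c(1, 10)), "threshold")
  t2 <- attr(cluster_threshold(base, c(1, 40)), "threshold")
  expect_gt(t1, t2)
  expect_error(cluster_threshold(base, df, p_form = 1.5),
               class = "atersp_input_error")

  # peak reporting with latency lookup
  f40[3, 2, 4] <- thr + 9
  cl2 <- cluster_threshold(f40, df, t_ms = seq(0, 900, by = 100))
  expect_equal(cl2[[1]]$peak_latency_ms, 300)
  expect_equal(unname(cl2[[1]]$peak_xyz), c(3, 2, 4))
})

test_that("cluster power extraction equals a loop-based mean", {
  d <- c(6, 6, 4)
  cl <- list(list(id = 1, k = 40, peak_F = 1, peak_xyz = c(1, 1, 1),
                  peak_latency_ms = 0,
                  voxels = as.matrix(expand.grid(1:4, 1:5, 1:2))))
  const <- array(2.5, d)
  single <- list(list(id = 1, k = 1, peak_F = 1, peak_xyz = c(2, 3, 1),
                      peak_latency_ms = 0,
                      voxels = matrix(c(2, 3, 1), 1)))
  imgs <- list(list(hessian = const, silk = const * 2))
  pw <- extract_cluster_power(cl, imgs)
  expect_equal(pw$mean_db, c(2.5, 5))
  set.seed(2)
  rnd <- array(rnorm(prod(d)), d)
  pw2 <- extract_cluster_power(single, list(list(a = rnd)))
  expect_equal(pw2$mean_db, rnd[2, 3, 1])
  v <- cl[[1]]$voxels
  oracle <- mean(vapply(seq_len(nrow(v)), function(i)
    rnd[v[i, 1], v[i, 2], v[i, 3]], numeric(1)))
  pw3 <- extract_cluster_power(cl, list(list(a = rnd)))
  expect_equal(pw3$mean_db, oracle, tolerance = 1e-12)
})
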