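# Cell labels: first letter = estimation condition (Hedonic, Sensory,
# No estimation), second = texture (Hessian, Silk).
CELL_LEVELS <- c("HH", "SH", "NH", "HS", "SS", "NS")

cell_label <- function(texture, condition) {
  paste0(c(sensory = "S", hedonic = "H", none = "N")[condition],
         c(hessian = "H", silk = "S")[texture])
}

#' First-level design matrix with condition dummies and touch covariates
#'
#' Builds the single-trial design: six dummy columns, one per texture x
#' estimation cell (HH, SH, NH, HS, SS, NS: first letter hedonic /
#' sensory / no-estimation, second hessian / silk), plus six parametric
#' regressors carrying each cell's trial-level friction+load summation,
#' mean-centred. Covariate value per trial is `median_friction_n +
#' median_load_g` (raw summation) or the sum of the per-subject
#' z-scores of both measures (`covariate_mode = "zsum"`, recommended
#' when units are incommensurate).
#'
#' Centring policies: `"grand"` (default) centres the modulator by its
#' grand mean before placement, so covariate columns stay zero outside
#' their cell, contrast estimates compare cells at a common covariate
#' level, and adding a constant to the modulator leaves contrasts
#' unchanged; `"column"` centres each placed column by its own mean
#' over all trials (zero column means, but dummy-contrast estimates
#' then depend on the modulator's origin); `"cell"` centres within
#' each cell (covariates orthogonal to their dummies, so dummy
#' estimates revert to raw, unadjusted cell means).
#'
#' @param trials accepted touch-trial rows (needs `texture`,
#'   `condition`, `median_friction_n`, `median_load_g`)
#' @param covariate_mode `"sum"` or `"zsum"`
#' @param centring `"column"`, `"grand"` or `"cell"`
#' @param covariates logical; `FALSE` omits the parametric regressors
#'   (dummies-only design)
#' @return object of class `design_matrix`: `X` (trials x 12 or
#'   trials x 6), `labels`, `cells` (per-trial cell label)
#' @export
build_design <- function(trials, covariate_mode = c("sum", "zsum"),
                         centring = c("grand", "column", "cell"),
                         covariates = TRUE) {
  covariate_mode <- match.arg(covariate_mode)
  centring <- match.arg(centring)
  cells <- cell_label(trials$texture, trials$condition)
  missing_cells <- setdiff(CELL_LEVELS, cells)
  if (length(missing_cells))
    stop_atersp("input", "no trials for cell(s): %s",
                paste(missing_cells, collapse = ", "))
  D <- sapply(CELL_LEVELS, function(cl) as.numeric(cells == cl))
  colnames(D) <- CELL_LEVELS
  if (!covariates)
    return(structure(list(X = D, labels = CELL_LEVELS, cells = cells),
                     class = "design_matrix"))
  s <- if (covariate_mode == "sum") {
    trials$median_friction_n + trials$median_load_g
  } else {
    as.numeric(scale(trials$median_friction_n)) +
      as.numeric(scale(trials$median_load_g))
  }
  if (anyNA(s))
    stop_atersp("input", "undefined friction/load medians in design input")
  C <- switch(centring,
    cell = D * stats::ave(s, cells, FUN = function(v) v - mean(v)),
    grand = D * (s - mean(s)),
    column = {
      M <- D * s
      sweep(M, 2, colMeans(M))
    })
  colnames(C) <- paste0("CV_", CELL_LEVELS)
  structure(list(X = cbind(D, C),
                 labels = c(CELL_LEVELS, colnames(C)), cells = cells),
            class = "design_matrix")
}

#' Contrast vectors of the five standard effects
#'
#' Weights over the design columns for: the texture main effect
#' (hessian minus silk, +/- 1/3 per cell so the contrast estimates a
#' mean dB difference); the two estimation contrasts (sensory minus
#' hedonic; hedonic minus no estimation); and the two interaction
#' pairs (sensory-hessian + hedonic-silk vs hedonic-hessian +
#' sensory-silk; hedonic-hessian + no-silk vs no-hessian +
#' hedonic-silk).
#'
#' @param design a [build_design()] result
#' @return named list of numeric contrast vectors (length =
#'   `ncol(design$X)`)
#' @export
paper_contrasts <- function(design) {
  w <- function(...) {
    v <- stats::setNames(numeric(length(design$labels)), design$labels)
    pairs <- list(...)
    for (p in pairs) v[p[[1]]] <- p[[2]]
    v
  }
  list(
    texture = w(list(c("HH", "SH", "NH"), 1 / 3),
                list(c("HS", "SS", "NS"), -1 / 3)),
    est_sens_vs_hed = w(list(c("SH", "SS"), 1 / 2),
                        list(c("HH", "HS"), -1 / 2)),
    est_hed_vs_none = w(list(c("HH", "HS"), 1 / 2),
                        list(c("NH", "NS"), -1 / 2)),
    inter_1 = w(list(c("SH", "HS"), 1 / 2), list(c("HH", "SS"), -1 / 2)),
    inter_2 = w(list(c("HH", "NS"), 1 / 2), list(c("NH", "HS"), -1 / 2))
  )
}

#' Fit the first-level GLM and form contrast images
#'
#' Ordinary least squares per voxel over the trial dimension:
#' `beta = (X'X)^-1 X'Y`, then one image `c' beta` per contrast.
#' Input images may be any shape (voxels are flattened); `NA` voxels
#' (outside the scalp mask) propagate.
#'
#' @param images numeric array, trials x voxel-dims (e.g. trials x nx
#'   x ny x T), or trials x V matrix
#' @param design a [build_design()] result (rows must match trials)
#' @param contrasts named list of contrast vectors
#'   ([paper_contrasts()] by default)
#' @return named list of contrast arrays (voxel-dims shape), plus
#'   attribute `beta` (coefficients x V matrix)
#' @export
fit_first_level <- function(images, design, contrasts = NULL) {
  X <- design$X
  d <- dim(images)
  if (d[1] != nrow(X))
    stop_atersp("input", "image count (%d) != design rows (%d)",
                d[1], nrow(X))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- design$labels[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_atersp("numeric", "rank-deficient design; offending column(s): %s",
                paste(bad, collapse = ", "))
  }
  if (is.null(contrasts)) contrasts <- paper_contrasts(design)
  vshape <- d[-1]
  Y <- matrix(images, d[1], prod(vshape))
  # normal equations (X has full rank, checked above)
  beta <- solve(crossprod(X), crossprod(X, Y))
  out <- lapply(contrasts, function(cv) {
    if (length(cv) != ncol(X))
      cv <- c(cv, numeric(ncol(X) - length(cv)))
    array(as.numeric(crossprod(cv, beta)), vshape)
  })
  attr(out, "beta") <- beta
  out
}

#' Second-level (group) F maps
#'
#' `one_sample`: per voxel, F = t^2 with t = mean / (SD / sqrt(n))
#' over subjects' contrast images, df = (1, n-1). `paired_two_contrast`:
#' both per-subject images of two contrast types are stacked
#' (N = 2n images) and a two-column group design (one mean per type)
#' is tested jointly against zero with an F-contrast on both columns,
#' df = (2, N-2).
#'
#' @param contrast_images for `one_sample`: list (or array) of
#'   per-subject contrast arrays; for `paired_two_contrast`: list of
#'   two such lists (one per contrast type, same subject order)
#' @param design `"one_sample"` or `"paired_two_contrast"`
#' @return list: `F` (voxel-shaped array), `df` (c(df1, df2)), `n`
#' @export
second_level_F <- function(contrast_images,
                           design = c("one_sample",
                                      "paired_two_contrast")) {
  design <- match.arg(design)
  stack <- function(lst) {
    a <- simplify2array(lst)                   # voxel-dims x n
    nd <- length(dim(a))
    aperm(a, c(nd, seq_len(nd - 1)))           # n x voxel-dims
  }
  if (design == "one_sample") {
    if (!is.list(contrast_images))
      stop_atersp("input", "one_sample expects a list of subject images")
    a <- stack(contrast_images)
    n <- dim(a)[1]
    if (n < 2) stop_atersp("input", "one_sample needs >= 2 subjects")
    vshape <- dim(a)[-1]
    m <- matrix(a, n, prod(vshape))
    mu <- colMeans(m)
    v <- (colSums(m^2) - n * mu^2) / (n - 1)
    v[v < 0] <- 0
    Fv <- n * mu^2 / v
    return(list(F = array(Fv, vshape), df = c(1, n - 1), n = n))
  }
  if (length(contrast_images) != 2)
    stop_atersp("input", "paired_two_contrast expects two image lists")
  n1 <- length(contrast_images[[1]])
  if (n1 != length(contrast_images[[2]]))
    stop_atersp("input", "mismatched subject sets between contrast types")
  a1 <- stack(contrast_images[[1]])
  a2 <- stack(contrast_images[[2]])
  vshape <- dim(a1)[-1]
  m <- rbind(matrix(a1, n1, prod(vshape)), matrix(a2, n1, prod(vshape)))
  N <- 2 * n1
  g1 <- colMeans(m[seq_len(n1), , drop = FALSE])
  g2 <- colMeans(m[n1 + seq_len(n1), , drop = FALSE])
  rss1 <- colSums(sweep(m[seq_len(n1), , drop = FALSE], 2, g1)^2) +
    colSums(sweep(m[n1 + seq_len(n1), , drop = FALSE], 2, g2)^2)
  rss0 <- colSums(m^2)
  Fv <- ((rss0 - rss1) / 2) / (rss1 / (N - 2))
  list(F = array(Fv, vshape), df = c(2, N - 2), n = n1)
}

neighbour_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dt = -1:1))
  off <- off[rowSums(off != 0) > 0, ]
  switch(as.character(connectivity),
         "6" = off[rowSums(abs(off)) == 1, , drop = FALSE],
         "18" = off[rowSums(abs(off)) <= 2, , drop = FALSE],
         "26" = off,
         stop_atersp("config", "connectivity must be 6, 18 or 26"))
}

#' Threshold an F map and extract space-time clusters
#'
#' Voxelwise threshold at the upper-tail F quantile for `p_form`, then
#' connected components among supra-threshold voxels (default
#' 18-connectivity: faces + edges, not corners); components smaller
#' than `k_min` voxels are discarded. Peak location ties break toward
#' the earliest latency, then lowest y, then lowest x.
#'
#' @param Fmap nx x ny x T array (NA allowed outside the mask)
#' @param df 2-vector of F degrees of freedom
#' @param t_ms frame times, ms (latency lookup); defaults to frame
#'   index
#' @param p_form cluster-forming (uncorrected) voxel threshold
#' @param k_min minimum cluster extent, voxels
#' @param connectivity 6, 18 or 26
#' @return list of clusters, each: `id`, `k`, `peak_F`, `peak_xyz`
#'   (grid indices), `peak_latency_ms`, `voxels` (k x 3 index matrix);
#'   attribute `threshold` carries the F cut-off
#' @export
cluster_threshold <- function(Fmap, df, t_ms = NULL, p_form = 0.001,
                              k_min = 35, connectivity = 18) {
  if (p_form <= 0 || p_form >= 1)
    stop_atersp("input", "p_form must be in (0, 1)")
  thr <- stats::qf(1 - p_form, df[1], df[2])
  d <- dim(Fmap)
  if (is.null(t_ms)) t_ms <- seq_len(d[3])
  supra <- which(!is.na(Fmap) & Fmap > thr)
  out <- list()
  if (length(supra)) {
    idx <- arrayInd(supra, d)
    key <- (idx[, 1] - 1) + d[1] * (idx[, 2] - 1) +
      d[1] * d[2] * (idx[, 3] - 1)
    pos <- new.env(hash = TRUE, size = length(supra))
    for (i in seq_along(key)) assign(as.character(key[i]), i, envir = pos)
    off <- neighbour_offsets(connectivity)
    comp <- integer(length(supra))
    nc <- 0
    queue <- integer(length(supra))
    for (i in seq_along(supra)) {
      if (comp[i]) next
      nc <- nc + 1
      queue[1] <- i
      head <- 1
      tail <- 1
      comp[i] <- nc
      while (head <= tail) {
        cur <- queue[head]
        head <- head + 1
        for (o in seq_len(nrow(off))) {
          nb <- idx[cur, ] + off[o, ]
          if (any(nb < 1) || any(nb > d)) next
          nk <- (nb[1] - 1) + d[1] * (nb[2] - 1) + d[1] * d[2] * (nb[3] - 1)
          j <- pos[[as.character(nk)]]
          if (!is.null(j) && !comp[j]) {
            comp[j] <- nc
            tail <- tail + 1
            queue[tail] <- j
          }
        }
      }
    }
    cid <- 0
    for (ci in seq_len(nc)) {
      members <- which(comp == ci)
      if (length(members) < k_min) next
      cid <- cid + 1
      vox <- idx[members, , drop = FALSE]
      fv <- Fmap[vox]
      best <- order(-fv, vox[, 3], vox[, 2], vox[, 1])[1]
      out[[cid]] <- list(id = cid, k = length(members),
                         peak_F = fv[best],
                         peak_xyz = vox[best, ],
                         peak_latency_ms = t_ms[vox[best, 3]],
                         voxels = vox)
    }
  }
  attr(out, "threshold") <- thr
  attr(out, "df") <- df
  out
}

#' Extract mean cluster power per subject and condition
#'
#' Averages each cluster's member voxels in every subject x condition
#' scalp-time image, yielding the tidy table used for post-hoc tests.
#'
#' @param clusters list from [cluster_threshold()]
#' @param images nested list: `images[[subject]][[condition]]` is an
#'   nx x ny x T array on the same grid as the F map
#' @return data.frame: `cluster`, `subject`, `condition`, `mean_db`
#' @export
extract_cluster_power <- function(clusters, images) {
  rows <- list()
  for (cl in clusters) {
    for (s in seq_along(images)) {
      for (cond in names(images[[s]])) {
        img <- images[[s]][[cond]]
        rows[[length(rows) + 1]] <- data.frame(
          cluster = cl$id, subject = s, condition = cond,
          mean_db = mean(img[cl$voxels], na.rm = TRUE))
      }
    }
  }
  if (!length(rows))
    return(data.frame(cluster = integer(0), subject = integer(0),
                      condition = character(0), mean_db = numeric(0)))
  do.call(rbind, rows)
}
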