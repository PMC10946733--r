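#' Project 3D electrode positions to the 2D scalp plane
#'
#' Azimuthal-equidistant ("flattened sphere") projection: each
#' electrode's 2D radius is proportional to its polar angle from the
#' vertex and its azimuth is preserved, so left/right and
#' anterior/posterior orderings survive. The projection is then
#' isotropically scaled (and shifted along y to the grid's centre) so
#' every channel lands inside the grid extents with a small margin.
#'
#' @param montage montage data.frame (`label`, `x_m`, `y_m`, `z_m`)
#' @param x_extent,y_extent grid extents, mm (left-right,
#'   posterior-anterior)
#' @param margin fraction of the half-extent kept free of electrodes
#' @return data.frame `label`, `x_mm`, `y_mm`
#' @export
project_electrodes <- function(montage, x_extent = c(-68, 68),
                               y_extent = c(-98, 72), margin = 0.05) {
  p <- as.matrix(montage[, c("x_m", "y_m", "z_m")])
  r <- sqrt(rowSums(p^2))
  if (any(r == 0) || stats::sd(p[, 3] / r) < 1e-12)
    stop_atersp("input", "degenerate montage: not spherical about a centre")
  theta <- acos(pmin(1, pmax(-1, p[, 3] / r)))   # polar angle from vertex
  az <- atan2(p[, 2], p[, 1])
  px <- theta * cos(az)
  py <- theta * sin(az)
  yc <- mean(y_extent)
  s <- (1 - margin) * min(
    max(x_extent) / max(abs(px)),
    (max(y_extent) - yc) / max(py),
    (yc - min(y_extent)) / max(-py))
  data.frame(label = montage$label, x_mm = s * px, y_mm = yc + s * py)
}

# --- Delaunay triangulation (Bowyer-Watson) -------------------------------
# No installed package provides 2D Delaunay triangulation, so a compact
# incremental implementation lives here; electrode layouts are small
# (<= a few hundred points) and in general position.

circumcircle <- function(ax, ay, bx, by, cx, cy) {
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) return(c(NA_real_, NA_real_, Inf))
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  c(ux, uy, sqrt((ux - ax)^2 + (uy - ay)^2))
}

delaunay <- function(x, y) {
  n <- length(x)
  if (n < 3) stop_atersp("input", "triangulation needs >= 3 points")
  # super-triangle enclosing everything
  cxm <- mean(range(x)); cym <- mean(range(y))
  span <- max(diff(range(x)), diff(range(y)), 1e-6) * 20
  px <- c(x, cxm - span, cxm + span, cxm)
  py <- c(y, cym - span, cym - span, cym + span)
  tris <- list(c(n + 1L, n + 2L, n + 3L))
  ccs <- list(circumcircle(px[n + 1], py[n + 1], px[n + 2], py[n + 2],
                           px[n + 3], py[n + 3]))
  for (i in seq_len(n)) {
    bad <- which(vapply(ccs, function(cc)
      (px[i] - cc[1])^2 + (py[i] - cc[2])^2 < cc[3]^2 * (1 + 1e-12),
      logical(1)))
    if (!length(bad)) next   # degenerate; point on hull of current mesh
    edges <- do.call(rbind, lapply(tris[bad], function(tr)
      rbind(sort(tr[c(1, 2)]), sort(tr[c(2, 3)]), sort(tr[c(1, 3)]))))
    key <- paste(edges[, 1], edges[, 2])
    boundary <- edges[key %in% names(which(table(key) == 1)), ,
                      drop = FALSE]
    tris[bad] <- NULL
    ccs[bad] <- NULL
    for (e in seq_len(nrow(boundary))) {
      tr <- c(boundary[e, ], i)
      cc <- circumcircle(px[tr[1]], py[tr[1]], px[tr[2]], py[tr[2]],
                         px[tr[3]], py[tr[3]])
      tris[[length(tris) + 1]] <- tr
      ccs[[length(ccs) + 1]] <- cc
    }
  }
  keep <- vapply(tris, function(tr) all(tr <= n), logical(1))
  out <- do.call(rbind, tris[keep])
  if (is.null(out) || !nrow(out))
    stop_atersp("input", "triangulation failed (collinear points?)")
  out
}

#' Scalp grid with interpolation weights
#'
#' Builds the standardised scalp-time grid: `nx x ny` pixels of size
#' `pixel_mm`, projects the montage onto it, triangulates the
#' projected electrodes, and precomputes for every pixel centre the
#' containing triangle's barycentric weights. Pixels outside the
#' electrode convex hull are masked (no extrapolation). The result
#' makes per-timepoint interpolation a single matrix product.
#'
#' @param montage montage data.frame
#' @param nx,ny grid dimensions, pixels
#' @param pixel_mm pixel size, mm (x, y)
#' @param x_extent,y_extent grid extents, mm
#' @return object of class `scalp_grid`: `electrodes` (projected 2D,
#'   mm), `px_x`/`px_y` (pixel-centre coordinates), `mask` (nx x ny
#'   logical), `W` (n_pixels x n_channels interpolation matrix,
#'   row-major over x then y), `tri` (triangle index matrix)
#' @export
scalp_grid <- function(montage, nx = 32, ny = 32,
                       pixel_mm = c(4.25, 5.38),
                       x_extent = c(-68, 68), y_extent = c(-98, 72)) {
  el <- project_electrodes(montage, x_extent, y_extent)
  if (nrow(el) < 3)
    stop_atersp("input", "need >= 3 channels for interpolation")
  tri <- delaunay(el$x_mm, el$y_mm)
  px_x <- x_extent[1] + pixel_mm[1] * (seq_len(nx) - 0.5)
  px_y <- y_extent[1] + pixel_mm[2] * (seq_len(ny) - 0.5)
  gx <- rep(px_x, times = ny)
  gy <- rep(px_y, each = nx)
  W <- matrix(0, nx * ny, nrow(el))
  inside <- rep(FALSE, nx * ny)
  eps <- 1e-9
  for (tr in seq_len(nrow(tri))) {
    a <- tri[tr, 1]; b <- tri[tr, 2]; cc <- tri[tr, 3]
    x1 <- el$x_mm[a]; y1 <- el$y_mm[a]
    x2 <- el$x_mm[b]; y2 <- el$y_mm[b]
    x3 <- el$x_mm[cc]; y3 <- el$y_mm[cc]
    det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    if (abs(det) < 1e-12) next
    l1 <- ((y2 - y3) * (gx - x3) + (x3 - x2) * (gy - y3)) / det
    l2 <- ((y3 - y1) * (gx - x3) + (x1 - x3) * (gy - y3)) / det
    l3 <- 1 - l1 - l2
    hit <- !inside & l1 >= -eps & l2 >= -eps & l3 >= -eps
    if (any(hit)) {
      W[hit, a] <- pmax(l1[hit], 0)
      W[hit, b] <- pmax(l2[hit], 0)
      W[hit, cc] <- pmax(l3[hit], 0)
      inside[hit] <- TRUE
    }
  }
  structure(list(electrodes = el, px_x = px_x, px_y = px_y,
                 nx = nx, ny = ny, pixel_mm = pixel_mm,
                 mask = matrix(inside, nx, ny), W = W, tri = tri),
            class = "scalp_grid")
}

#' Interpolate channel values onto the scalp grid
#'
#' Piecewise-linear (barycentric, triangulation-based) interpolation
#' of one scalar per channel at the pixel centres; out-of-hull pixels
#' are `NA`.
#'
#' @param values numeric vector, one value per channel (montage order)
#' @param grid a [scalp_grid()]
#' @return `nx x ny` matrix (x indexes rows: left to right; y indexes
#'   columns: posterior to anterior)
#' @export
interpolate_to_grid <- function(values, grid) {
  if (length(values) != ncol(grid$W))
    stop_atersp("input", "expected %d channel values, got %d",
                ncol(grid$W), length(values))
  v <- as.numeric(grid$W %*% values)
  v[!grid$mask] <- NA_real_
  matrix(v, grid$nx, grid$ny)
}

#' Build a scalp-time image from a band map
#'
#' Converts one trial's channels x time band ERSP into the 3D
#' scalp-time voxel representation: each timepoint's channel values
#' are interpolated onto the scalp grid and the planes stacked along
#' time. Optionally block-averages the time axis to `image_hz` first
#' (coarser voxel spacing for reduced-resolution analyses).
#'
#' @param bp a `band_power` object (see [band_maps()])
#' @param grid a [scalp_grid()]
#' @param trial trial index within `bp`
#' @param image_hz optional output frame rate; `NULL` keeps the
#'   resampled EEG rate
#' @return list: `data` (nx x ny x T array, dB; `NA` outside the
#'   mask), `t_ms` (frame centres), `dt_ms`
#' @export
scalp_time_image <- function(bp, grid, trial = 1, image_hz = NULL) {
  v <- array(bp$data[trial, , ], dim(bp$data)[2:3])   # ch x time
  t_ms <- bp$t_ms
  if (!is.null(image_hz) && image_hz < bp$fs) {
    k <- floor(bp$fs / image_hz)
    m <- ncol(v) %/% k
    v <- t(block_average(t(v[, seq_len(m * k), drop = FALSE]), bp$fs,
                         bp$fs / k))
    t_ms <- block_average(t_ms[seq_len(m * k)], bp$fs, bp$fs / k)
  }
  g <- grid$W %*% v                                   # pixels x time
  g[!grid$mask, ] <- NA_real_
  list(data = array(g, c(grid$nx, grid$ny, ncol(v))), t_ms = t_ms,
       dt_ms = if (length(t_ms) > 1) diff(t_ms[1:2]) else NA_real_)
}

# Batched scalp-time images: interpolate, time-decimate and smooth
# every trial of a band map in a handful of matrix products. The mask
# normalisation kernel is shared by all trials. Returns trials x
# (nx*ny*T) matrix of smoothed voxels (x fastest, then y, then t) plus
# the frame times.
scalp_time_images_smoothed <- function(bp, grid, image_hz = NULL,
                                       fwhm = c(9, 9, 20)) {
  d <- dim(bp$data)                 # trials x ch x time
  t_ms <- bp$t_ms
  maps <- bp$data
  if (!is.null(image_hz) && image_hz < bp$fs) {
    k <- floor(bp$fs / image_hz)
    m <- d[3] %/% k
    idx <- seq_len(m * k)
    # block-average frames: collapse (trial*ch) x time
    flat <- matrix(aperm(maps[, , idx, drop = FALSE], c(3, 1, 2)),
                   nrow = m * k)
    dec <- block_average(flat, bp$fs, bp$fs / k)      # m x (tr*ch)
    maps <- aperm(array(dec, c(m, d[1], d[2])), c(2, 3, 1))
    t_ms <- block_average(t_ms[idx], bp$fs, bp$fs / k)
  }
  Tf <- dim(maps)[3]
  dt_ms <- if (Tf > 1) diff(t_ms[1:2]) else 1000 / bp$fs
  nx <- grid$nx; ny <- grid$ny
  npix <- nx * ny
  V <- matrix(aperm(maps, c(2, 3, 1)), nrow = d[2])   # ch x (Tf*tr)
  G <- grid$W %*% V
  G[!grid$mask, ] <- 0
  sig <- fwhm / sqrt(8 * log(2)) / c(grid$pixel_mm, dt_ms)
  Kx <- gauss_conv_matrix(nx, sig[1])
  Ky <- gauss_conv_matrix(ny, sig[2])
  Kt <- gauss_conv_matrix(Tf, sig[3])
  sm_xy <- function(P, nframe) {
    a <- array(Kx %*% matrix(P, nx, ny * nframe), c(nx, ny, nframe))
    a <- aperm(array(Ky %*% matrix(aperm(a, c(2, 1, 3)),
                                   ny, nx * nframe),
                     c(ny, nx, nframe)), c(2, 1, 3))
    matrix(a, npix, nframe)
  }
  num <- sm_xy(G, Tf * d[1])
  num <- array(num, c(npix, Tf, d[1]))
  num <- aperm(num, c(1, 3, 2))                       # pix x tr x Tf
  num <- array(matrix(num, npix * d[1], Tf) %*% t(Kt),
               c(npix, d[1], Tf))
  mk <- matrix(as.numeric(grid$mask), npix, Tf)
  den <- sm_xy(mk, Tf)
  den <- matrix(den, npix, Tf) %*% t(Kt)
  den[den < 1e-12] <- NA_real_
  out <- matrix(NA_real_, d[1], npix * Tf)
  den_v <- as.numeric(den)
  inmask <- rep(grid$mask, times = Tf)
  for (i in seq_len(d[1])) {
    v <- as.numeric(num[, i, ]) / den_v
    v[!inmask] <- NA_real_
    out[i, ] <- v
  }
  list(M = out, vshape = c(nx, ny, Tf), t_ms = t_ms, dt_ms = dt_ms)
}

gauss_conv_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  d <- outer(seq_len(n), seq_len(n), "-")
  k <- exp(-d^2 / (2 * sigma^2))
  k[abs(d) > ceiling(4 * sigma)] <- 0
  k
}

#' Smooth a scalp-time image with an anisotropic Gaussian kernel
#'
#' Separable Gaussian smoothing with full-widths at half-maximum given
#' in millimetres (x, y) and milliseconds (t); sigma = FWHM /
#' sqrt(8 ln 2) per axis, converted to voxel units. Masked (outside
#' scalp) voxels are excluded by mask-weighted (renormalised)
#' convolution, so a constant in-mask image is reproduced exactly and
#' edges are not attenuated.
#'
#' @param img nx x ny x T array (NA outside the mask) or the list
#'   returned by [scalp_time_image()]
#' @param fwhm 3-vector: FWHM in mm, mm, ms
#' @param voxel 3-vector: voxel size in mm, mm, ms
#' @return smoothed array of the same shape (NA pattern preserved)
#' @export
smooth_gaussian <- function(img, fwhm = c(9, 9, 20),
                            voxel = c(4.25, 5.38, 1000 / 256)) {
  if (is.list(img)) {
    voxel[3] <- img$dt_ms
    img <- img$data
  }
  if (any(fwhm <= 0)) stop_atersp("input", "FWHM must be > 0")
  sig <- fwhm / sqrt(8 * log(2)) / voxel
  d <- dim(img)
  Kx <- gauss_conv_matrix(d[1], sig[1])
  Ky <- gauss_conv_matrix(d[2], sig[2])
  Kt <- gauss_conv_matrix(d[3], sig[3])
  mask <- !is.na(img)
  x0 <- ifelse(mask, img, 0)
  sm3 <- function(a) {
    a <- array(Kx %*% matrix(a, d[1], d[2] * d[3]), d)          # x axis
    a <- aperm(array(Ky %*% matrix(aperm(a, c(2, 1, 3)),
                                   d[2], d[1] * d[3]),
                     c(d[2], d[1], d[3])), c(2, 1, 3))          # y axis
    array(matrix(a, d[1] * d[2], d[3]) %*% t(Kt), d)            # t axis
  }
  num <- sm3(x0)
  den <- sm3(mask + 0)
  out <- num / den
  out[!mask] <- NA_real_
  out
}
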