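#' Complex Morlet wavelet kernel
#'
#' A complex sine wave tapered by a Gaussian with
#' `sigma_t = n_cycles / (2*pi*f)`, truncated at +/- 3 sigma and
#' normalised to unit energy (L2). The log-ratio baseline makes the
#' downstream ERSP invariant to this normalisation.
#'
#' @param f centre frequency, Hz
#' @param fs sampling rate, Hz
#' @param n_cycles cycles per wavelet (time-frequency trade-off)
#' @return complex vector of odd length; attribute `half` gives the
#'   half-support in samples
#' @export
morlet_wavelet <- function(f, fs, n_cycles = 5) {
  sigma_t <- n_cycles / (2 * pi * f)
  half <- as.integer(ceiling(3 * sigma_t * fs))
  t <- (-half:half) / fs
  w <- exp(-t^2 / (2 * sigma_t^2)) * exp(2i * pi * f * t)
  w <- w / sqrt(sum(Mod(w)^2))
  attr(w, "half") <- half
  w
}

# Reflective padding of the columns-as-time matrix x (ch x n) by `pad`.
reflect_pad <- function(x, pad) {
  n <- ncol(x)
  if (pad >= n) stop_atersp("input", "epoch shorter than wavelet support")
  cbind(x[, (pad + 1):2, drop = FALSE], x,
        x[, (n - 1):(n - pad), drop = FALSE])
}

# Morlet power of one channels x samples matrix. Returns channels x
# freqs x samples array plus the per-frequency edge half-support.
morlet_power_matrix <- function(x, fs, freqs, n_cycles = 5,
                                method = c("fft", "direct")) {
  method <- match.arg(method)
  kerns <- lapply(freqs, morlet_wavelet, fs = fs, n_cycles = n_cycles)
  halves <- vapply(kerns, attr, integer(1), "half")
  pad <- max(halves)
  n <- ncol(x)
  if (n <= 2 * pad)
    stop_atersp("input",
                "epoch (%d samples) shorter than twice the widest wavelet (%d)",
                n, pad)
  xp <- reflect_pad(x, pad)
  np <- ncol(xp)
  out <- array(NA_real_, c(nrow(x), length(freqs), n))
  if (method == "fft") {
    nfft <- stats::nextn(np + 2 * pad + 1, c(2, 3, 5))
    XF <- stats::mvfft(t(cbind(xp, matrix(0, nrow(x), nfft - np))))
    for (k in seq_along(freqs)) {
      kw <- kerns[[k]]
      h <- halves[k]
      kf <- stats::fft(c(kw, rep(0, nfft - length(kw))))
      y <- stats::mvfft(XF * kf, inverse = TRUE) / nfft
      # "same" alignment: kernel centre at lag h; strip the pad
      idx <- h + pad + seq_len(n)
      out[, k, ] <- t(Mod(y[idx, , drop = FALSE])^2)
    }
  } else {
    for (k in seq_along(freqs)) {
      kw <- kerns[[k]]
      h <- halves[k]
      L <- length(kw)
      for (ch in seq_len(nrow(x))) {
        y <- complex(n)
        for (s in seq_len(n)) {
          seg <- xp[ch, (s + pad - h):(s + pad + h)]
          y[s] <- sum(seg * rev(kw))
        }
        out[ch, k, ] <- Mod(y)^2
      }
    }
  }
  attr(out, "edge_half") <- halves
  out
}

#' Morlet time-frequency power of epoched EEG
#'
#' Convolves every trial and channel with complex Morlet wavelets and
#' returns squared-magnitude power. Convolution runs in the frequency
#' domain with reflective padding; `method = "direct"` is a plain
#' time-domain convolution retained for verification. Samples closer
#' to an epoch edge than a wavelet's half-support (3 sigma_t) are
#' edge-contaminated; their count per frequency is stored in
#' `edge_half` and honoured by [logratio_baseline()].
#'
#' @param ep an `eeg_epochs` object (or a channels x samples matrix
#'   plus `fs`)
#' @param freqs frequencies, Hz (default 1-40 in 1-Hz steps)
#' @param n_cycles wavelet cycles
#' @param method `"fft"` or `"direct"`
#' @param fs sampling rate, required when `ep` is a bare matrix
#' @return object of class `tf_power`: `power` (trials x channels x
#'   freqs x samples, microvolts squared), `freqs`, `t_ms`, `fs`,
#'   `edge_half` (samples per frequency), `labels`
#' @export
morlet_power <- function(ep, freqs = 1:40, n_cycles = 5,
                         method = c("fft", "direct"), fs = NULL) {
  method <- match.arg(method)
  if (is.matrix(ep)) {
    if (is.null(fs)) stop_atersp("input", "fs required for matrix input")
    p <- morlet_power_matrix(ep, fs, freqs, n_cycles, method)
    dat <- array(p, c(1, dim(p)))
    attr(dat, "edge_half") <- attr(p, "edge_half")
    return(structure(list(power = dat, freqs = freqs,
                          t_ms = (seq_len(ncol(ep)) - 1) / fs * 1000,
                          fs = fs, n_cycles = n_cycles,
                          edge_half = attr(p, "edge_half"),
                          labels = NULL, scale = "power"),
                     class = "tf_power"))
  }
  d <- dim(ep$data)
  out <- array(NA_real_, c(d[1], d[2], length(freqs), d[3]))
  eh <- NULL
  for (i in seq_len(d[1])) {
    m <- array(ep$data[i, , ], c(d[2], d[3]))
    p <- morlet_power_matrix(m, ep$fs, freqs, n_cycles, method)
    out[i, , , ] <- p
    eh <- attr(p, "edge_half")
  }
  structure(list(power = out, freqs = freqs, t_ms = ep$t_ms, fs = ep$fs,
                 n_cycles = n_cycles, edge_half = eh,
                 labels = ep$labels, scale = "power"),
            class = "tf_power")
}

#' Log-ratio baseline normalisation (ERSP in dB)
#'
#' Rescales power as `10*log10(P(t) / mean(P(baseline)))` per trial,
#' channel and frequency, with the baseline mean taken over time
#' within the window. Edge-contaminated samples are excluded from the
#' baseline mean; a frequency whose entire baseline window is
#' edge-contaminated, or whose baseline power is zero, raises a
#' labelled numerical error.
#'
#' @param tf a `tf_power` object on the power scale
#' @param baseline 2-vector, ms (window relative to movement onset)
#' @param log_mode `"db"` (10*log10) or `"ln"` (natural log ratio)
#' @return `tf_power` with `power` in dB (`scale` set accordingly)
#' @export
logratio_baseline <- function(tf, baseline = c(-4000, -2000),
                              log_mode = c("db", "ln")) {
  log_mode <- match.arg(log_mode)
  if (!identical(tf$scale, "power"))
    stop_atersp("input", "input is already baseline-normalised")
  nt <- length(tf$t_ms)
  d <- dim(tf$power)
  for (k in seq_along(tf$freqs)) {
    h <- tf$edge_half[k]
    valid <- rep(TRUE, nt)
    if (h > 0) valid[c(seq_len(min(h, nt)),
                       seq.int(max(1, nt - h + 1), nt))] <- FALSE
    bl <- which(tf$t_ms >= baseline[1] & tf$t_ms <= baseline[2] & valid)
    if (!length(bl))
      stop_atersp("numeric",
                  "no edge-clean baseline samples at %g Hz", tf$freqs[k])
    pb <- tf$power[, , k, bl, drop = FALSE]
    blm <- apply(pb, c(1, 2), mean)
    if (any(blm <= 0))
      stop_atersp("numeric", "zero baseline power at %g Hz", tf$freqs[k])
    ratio <- tf$power[, , k, , drop = FALSE] /
      array(blm, c(d[1], d[2], 1, d[4]))
    tf$power[, , k, ] <- if (log_mode == "db") 10 * log10(ratio)
                         else log(ratio)
  }
  tf$scale <- if (log_mode == "db") "dB" else "ln-ratio"
  tf$baseline <- baseline
  tf
}

#' Band-average and crop an ERSP
#'
#' Arithmetic mean of the dB values over the band's frequency bins
#' (averaging is performed on the dB scale, after the log-ratio),
#' then cropped to the analysis window.
#'
#' @param tf a `tf_power` object in dB
#' @param band 2-vector of band edges in Hz (inclusive), or `"alpha"`
#'   (8-12) / `"beta"` (16-24)
#' @param crop 2-vector, ms
#' @return object of class `band_power`: `data` (trials x channels x
#'   time, dB), `t_ms`, `band`, `fs`, `labels`
#' @export
band_average_crop <- function(tf, band, crop = c(0, 4000)) {
  if (is.character(band))
    band <- switch(band, alpha = c(8, 12), beta = c(16, 24),
                   stop_atersp("input", "unknown band '%s'", band))
  bins <- which(tf$freqs >= band[1] & tf$freqs <= band[2])
  if (!length(bins))
    stop_atersp("input", "band %g-%g Hz matches no frequency bins",
                band[1], band[2])
  ts <- which(tf$t_ms >= crop[1] & tf$t_ms <= crop[2])
  sub <- tf$power[, , bins, ts, drop = FALSE]
  dat <- apply(sub, c(1, 2, 4), mean)
  structure(list(data = dat, t_ms = tf$t_ms[ts], band = band,
                 fs = tf$fs, labels = tf$labels, scale = tf$scale),
            class = "band_power")
}

#' Per-trial band ERSP maps, computed in trial chunks
#'
#' Memory-lean driver equivalent to [morlet_power()] +
#' [logratio_baseline()] + [band_average_crop()] for one or more
#' bands: trials are processed in chunks whose (trial, channel) rows
#' share one FFT pass, and only the band averages are retained.
#'
#' @param ep an `eeg_epochs` object
#' @param bands named list of band edges, e.g.
#'   `list(alpha = c(8, 12), beta = c(16, 24))`
#' @param freqs wavelet frequencies; defaults to the union of integer
#'   bins covering the requested bands (pass `1:40` for the full set)
#' @param n_cycles wavelet cycles
#' @param baseline,crop windows in ms
#' @param log_mode see [logratio_baseline()]
#' @param chunk_trials trials decomposed per FFT batch (memory /
#'   speed trade-off)
#' @return named list of `band_power` objects
#' @export
band_maps <- function(ep, bands = list(alpha = c(8, 12),
                                       beta = c(16, 24)),
                      freqs = NULL, n_cycles = 5,
                      baseline = c(-4000, -2000), crop = c(0, 4000),
                      log_mode = "db", chunk_trials = 24) {
  if (is.null(freqs))
    freqs <- sort(unique(unlist(lapply(bands, function(b)
      seq(ceiling(b[1]), floor(b[2]))))))
  d <- dim(ep$data)
  ts <- which(ep$t_ms >= crop[1] & ep$t_ms <= crop[2])
  out <- lapply(bands, function(b)
    array(NA_real_, c(d[1], d[2], length(ts))))
  bin_of <- lapply(bands, function(b)
    which(freqs >= b[1] & freqs <= b[2]))
  for (b in names(bands)) if (!length(bin_of[[b]]))
    stop_atersp("input", "band '%s' matches no frequency bins", b)
  kerns <- lapply(freqs, morlet_wavelet, fs = ep$fs, n_cycles = n_cycles)
  halves <- vapply(kerns, attr, integer(1), "half")
  pad <- max(halves)
  if (d[3] <= 2 * pad)
    stop_atersp("input", "epoch shorter than twice the widest wavelet")
  nfft <- stats::nextn(d[3] + 4 * pad + 1, c(2, 3, 5))
  kf <- lapply(seq_along(freqs), function(k)
    stats::fft(c(kerns[[k]], rep(0, nfft - length(kerns[[k]])))))
  starts <- seq(1, d[1], by = chunk_trials)
  for (s0 in starts) {
    tr <- s0:min(s0 + chunk_trials - 1, d[1])
    # stack (time x channel x trial), reflect-pad, one FFT per column
    m <- matrix(aperm(ep$data[tr, , , drop = FALSE], c(3, 2, 1)),
                nrow = d[3])
    mp <- rbind(m[(pad + 1):2, , drop = FALSE], m,
                m[(d[3] - 1):(d[3] - pad), , drop = FALSE],
                matrix(0, nfft - d[3] - 2 * pad, ncol(m)))
    MF <- stats::mvfft(mp)
    acc <- lapply(bands, function(b) 0)
    for (k in seq_along(freqs)) {
      h <- halves[k]
      valid <- rep(TRUE, d[3])
      if (h > 0) valid[c(seq_len(min(h, d[3])),
                         seq.int(max(1, d[3] - h + 1), d[3]))] <- FALSE
      bl <- which(ep$t_ms >= baseline[1] & ep$t_ms <= baseline[2] & valid)
      if (!length(bl))
        stop_atersp("numeric", "no edge-clean baseline samples at %g Hz",
                    freqs[k])
      y <- stats::mvfft(MF * kf[[k]], inverse = TRUE) / nfft
      pk <- Mod(y[h + pad + seq_len(d[3]), , drop = FALSE])^2  # t x rows
      blm <- colMeans(pk[bl, , drop = FALSE])
      if (any(blm <= 0))
        stop_atersp("numeric", "zero baseline power at %g Hz", freqs[k])
      ratio <- pk[ts, , drop = FALSE] / rep(blm, each = length(ts))
      dB <- if (log_mode == "db") 10 * log10(ratio) else log(ratio)
      for (b in names(bands)) if (k %in% bin_of[[b]])
        acc[[b]] <- acc[[b]] + dB
    }
    for (b in names(bands)) {
      avg <- acc[[b]] / length(bin_of[[b]])   # time x (ch, trial)
      out[[b]][tr, , ] <- aperm(array(avg, c(length(ts), d[2],
                                             length(tr))), c(3, 2, 1))
    }
  }
  lapply(stats::setNames(names(bands), names(bands)), function(b)
    structure(list(data = out[[b]], t_ms = ep$t_ms[ts],
                   band = bands[[b]], fs = ep$fs, labels = ep$labels,
                   scale = if (log_mode == "db") "dB" else "ln-ratio"),
              class = "band_power"))
}
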