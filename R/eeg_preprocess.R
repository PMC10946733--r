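#' EEG recording container
#'
#' A light container for a continuous multichannel recording: a
#' channels x samples matrix in microvolts, the sampling rate and the
#' electrode montage. The reference electrode is assumed absent from
#' the array (recording channels only).
#'
#' @param data channels x samples numeric matrix, microvolts
#' @param fs sampling rate, Hz
#' @param montage montage data.frame (`label`, `x_m`, `y_m`, `z_m`);
#'   row count must match `nrow(data)`
#' @return object of class `eeg_recording`
#' @export
eeg_recording <- function(data, fs, montage) {
  if (!is.matrix(data)) stop_atersp("input", "data must be a matrix")
  if (nrow(data) != nrow(montage))
    stop_atersp("input", "channel count (%d) != montage rows (%d)",
                nrow(data), nrow(montage))
  if (fs <= 0) stop_atersp("input", "fs must be > 0")
  rownames(data) <- montage$label
  structure(list(data = data, fs = fs, montage = montage,
                 provenance = list()),
            class = "eeg_recording")
}

#' Read an EEG fixture TSV
#'
#' Reads the plain-text channel fixture format written by
#' [generate_study()]: one column per channel with a header row of
#' channel names, samples in rows, microvolts.
#'
#' @param path TSV path
#' @param fs sampling rate, Hz (not stored in the fixture)
#' @param montage montage data.frame; column order is matched to
#'   `montage$label`
#' @return an [eeg_recording()]
#' @export
read_eeg_tsv <- function(path, fs, montage) {
  df <- read_tsv(path)
  missing <- setdiff(montage$label, names(df))
  if (length(missing))
    stop_atersp("io", "EEG file '%s' lacks channels: %s", path,
                paste(utils::head(missing, 5), collapse = ", "))
  eeg_recording(t(as.matrix(df[, montage$label])), fs, montage)
}

#' Band-pass and notch filter a raw recording
#'
#' Zero-phase (forward-backward) IIR filtering: Butterworth high-pass
#' and low-pass applied in cascade plus a band-stop notch. Defaults
#' follow the conventional active-touch EEG setup: 1-100 Hz band-pass
#' with a 50 +/- 2 Hz mains notch. The filter family and orders are
#' recorded in the recording's provenance list.
#'
#' @param rec an [eeg_recording()] with `fs >= 256`
#' @param l_freq,h_freq band-pass edges, Hz
#' @param notch 2-vector band-stop edges, Hz, or NULL to skip
#' @param order Butterworth order for each stage (effective order
#'   doubles under forward-backward application)
#' @return filtered [eeg_recording()]
#' @export
filter_raw <- function(rec, l_freq = 1, h_freq = 100,
                       notch = c(48, 52), order = 4) {
  if (rec$fs < 256)
    stop_atersp("input",
                "fs = %g Hz too low for the %g-Hz low-pass (need >= 256)",
                rec$fs, h_freq)
  nyq <- rec$fs / 2
  hp <- signal::butter(order %/% 2, l_freq / nyq, type = "high")
  lp <- signal::butter(order, h_freq / nyq, type = "low")
  bs <- if (!is.null(notch)) signal::butter(2, notch / nyq, type = "stop")
  filt_one <- function(x) {
    x <- signal::filtfilt(hp, x)
    x <- signal::filtfilt(lp, x)
    if (!is.null(bs)) x <- signal::filtfilt(bs, x)
    x
  }
  rec$data <- t(apply(rec$data, 1, filt_one))
  rec$provenance <- c(rec$provenance, list(filter = list(
    family = "butterworth", zero_phase = TRUE,
    highpass_hz = l_freq, highpass_order = order %/% 2,
    lowpass_hz = h_freq, lowpass_order = order,
    notch_hz = notch, notch_order = 2)))
  rec
}

#' Epoch a recording around per-trial movement onsets
#'
#' Fuses the touch-derived movement-onset markers with the EEG: each
#' accepted trial's onset time (cue time plus detected onset latency,
#' both on the shared recording clock, plus an optional constant
#' offset) becomes time zero of an epoch spanning `tmin`..`tmax`
#' seconds. Trials whose window falls outside the recording are
#' dropped, with the reason kept in the `dropped` attribute.
#'
#' @param rec an [eeg_recording()]
#' @param touch_trials touch-trial table ([process_sensor()]); only
#'   accepted rows are epoched
#' @param events events table with `trial` and `cue_time_ms`
#' @param tmin,tmax epoch window, seconds relative to movement onset
#' @param clock_offset_ms constant EEG-minus-sensor clock offset
#' @return object of class `eeg_epochs`: `data` (trials x channels x
#'   samples), `t_ms`, `fs`, `labels` (per-trial data.frame), `montage`
#' @export
epoch_to_onsets <- function(rec, touch_trials, events,
                            tmin = -5.5, tmax = 5, clock_offset_ms = 0) {
  acc <- touch_trials[touch_trials$accepted, ]
  if (!nrow(acc)) stop_atersp("input", "no accepted trials to epoch")
  cue <- events$cue_time_ms[match(acc$trial, events$trial)]
  onset_global <- cue + acc$onset_ms + clock_offset_ms
  n <- ncol(rec$data)
  i0 <- round(onset_global / 1000 * rec$fs) + 1
  lo <- i0 + round(tmin * rec$fs)
  hi <- i0 + round(tmax * rec$fs)
  keep <- lo >= 1 & hi <= n
  dropped <- acc$trial[!keep]
  if (!any(keep)) stop_atersp("input", "every epoch exceeds the recording")
  nsamp <- hi[1] - lo[1] + 1
  dat <- array(NA_real_, c(sum(keep), nrow(rec$data), nsamp))
  ki <- which(keep)
  for (j in seq_along(ki)) {
    dat[j, , ] <- rec$data[, lo[ki[j]]:hi[ki[j]]]
  }
  labels <- acc[keep, c("subject", "trial", "block", "texture",
                        "condition", "onset_ms",
                        "median_speed_mms", "median_friction_n",
                        "median_load_g")]
  rownames(labels) <- NULL
  structure(list(data = dat,
                 t_ms = (seq_len(nsamp) - 1 + round(tmin * rec$fs)) /
                   rec$fs * 1000,
                 fs = rec$fs, labels = labels, montage = rec$montage,
                 dropped = dropped),
            class = "eeg_epochs")
}

# Fourier resampling of the columns of a matrix: the spectrum is
# truncated at the new Nyquist frequency (ideal anti-alias filter for
# the retained band) and inverted at the new length.
resample_fft <- function(m, n_out) {
  n <- nrow(m)
  X <- stats::mvfft(m)
  K <- min(n_out, n)
  half <- (K - 1) %/% 2
  Y <- matrix(0 + 0i, n_out, ncol(m))
  Y[1, ] <- X[1, ]
  if (half > 0) {
    Y[1 + seq_len(half), ] <- X[1 + seq_len(half), , drop = FALSE]
    Y[n_out + 1 - seq_len(half), ] <- X[n + 1 - seq_len(half), ,
                                        drop = FALSE]
  }
  Re(stats::mvfft(Y, inverse = TRUE)) / n
}

#' Downsample epochs with anti-alias filtering
#'
#' Fourier-domain resampling of every trial and channel to `target`
#' Hz: the spectrum is truncated at the new Nyquist frequency (an
#' ideal anti-aliasing low-pass) and inverted at the new length.
#' Labels are preserved and the time axis recomputed; the epoch
#' duration is preserved to within one output sample.
#'
#' @param ep an `eeg_epochs` object
#' @param target target rate, Hz; must be < `ep$fs`
#' @return resampled `eeg_epochs`
#' @export
downsample_epochs <- function(ep, target = 256) {
  if (target >= ep$fs)
    stop_atersp("input", "target (%g) must be below fs (%g)", target, ep$fs)
  d <- dim(ep$data)
  n_out <- round(d[3] * target / ep$fs)
  flat <- matrix(aperm(ep$data, c(3, 1, 2)), nrow = d[3])
  res <- resample_fft(flat, n_out)
  ep$data <- aperm(array(res, c(n_out, d[1], d[2])), c(2, 3, 1))
  ep$t_ms <- ep$t_ms[1] + (seq_len(n_out) - 1) * 1000 / target
  ep$fs <- target
  ep
}

#' Common average reference
#'
#' Subtracts, at every timepoint of every trial, the instantaneous
#' mean over channels; the across-channel mean of the result is zero
#' (idempotent).
#'
#' @param ep an `eeg_epochs` object with >= 2 channels
#' @return re-referenced `eeg_epochs`
#' @export
common_average_reference <- function(ep) {
  if (dim(ep$data)[2] < 2)
    stop_atersp("input", "common average reference needs >= 2 channels")
  m <- colMeans(aperm(ep$data, c(2, 1, 3)))   # trials x samples
  ep$data <- ep$data - aperm(
    array(m, c(dim(m), dim(ep$data)[2])), c(1, 3, 2))
  ep
}

#' Peak-to-peak amplitude artifact rejection
#'
#' Drops trials whose peak-to-peak amplitude exceeds the threshold on
#' any channel. A stand-in for manual artifact inspection; synthetic
#' data only contain such excursions when spikes are injected.
#'
#' @param ep an `eeg_epochs` object
#' @param threshold_uV rejection threshold, microvolts (> 0; `Inf`
#'   disables rejection)
#' @return `eeg_epochs` without the rejected trials; attribute
#'   `n_rejected` carries the count
#' @export
amplitude_artifact_reject <- function(ep, threshold_uV = 500) {
  if (threshold_uV <= 0) stop_atersp("input", "threshold must be > 0")
  d <- dim(ep$data)
  m <- t(matrix(aperm(ep$data, c(3, 1, 2)), nrow = d[3]))
  hi <- m[cbind(seq_len(nrow(m)), max.col(m))]
  lo <- m[cbind(seq_len(nrow(m)), max.col(-m))]
  pp_tc <- matrix(hi - lo, d[1], d[2])       # trials x channels
  keep <- apply(pp_tc, 1, max) <= threshold_uV
  if (!any(keep))
    stop_atersp("input",
                "all %d trials exceed %g uV peak-to-peak; review threshold",
                length(keep), threshold_uV)
  ep$data <- ep$data[keep, , , drop = FALSE]
  ep$labels <- ep$labels[keep, ]
  rownames(ep$labels) <- NULL
  attr(ep, "n_rejected") <- sum(!keep)
  ep
}
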