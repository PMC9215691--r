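#' Downsample an EEG segment
#'
#' Fourier resampling: the spectrum is truncated at the new Nyquist
#' frequency (which is the anti-alias step) and inverted on the coarser
#' grid. This is exact for band-limited signals, delay-free, and supports
#' non-integer rate ratios such as 512 -> 250 Hz.
#'
#' @param seg An [eeg_segment()].
#' @param target_fs Desired sampling rate (Hz), at most `seg$fs`.
#' @return The resampled segment with `round(samples * target_fs / fs)`
#'   samples. When `target_fs == fs` the segment is returned unchanged.
#' @export
downsample <- function(seg, target_fs) {
  stopifnot(inherits(seg, "eeg_segment"))
  if (target_fs > seg$fs)
    stop("target_fs (", target_fs, ") exceeds the segment's fs (", seg$fs, ")")
  if (target_fs == seg$fs) return(seg)
  n_out <- round(n_samples(seg) * target_fs / seg$fs)
  out <- t(apply(seg$data, 1, fourier_resample, n_out = n_out))
  eeg_segment(out, fs = target_fs, channel_labels = seg$channel_labels,
              subject_id = seg$subject_id, segment_id = seg$segment_id)
}

# Resample by spectral truncation to n_out points (n_out <= length(x)).
fourier_resample <- function(x, n_out) {
  n <- length(x)
  X <- fft(x)
  h <- ceiling(n_out / 2)          # DC + positive-frequency bins kept
  Y <- complex(n_out)
  Y[seq_len(h)] <- X[seq_len(h)]
  neg <- n_out - h
  if (neg > 0) Y[(h + 1):n_out] <- X[(n - neg + 1):n]
  Re(fft(Y, inverse = TRUE)) / n
}

#' Band-pass filter in the low alpha band
#'
#' Fourth-order Butterworth band-pass applied forward and backward
#' (zero-phase; the effective magnitude response is the squared Butterworth
#' response of the stated order).
#'
#' @param seg An [eeg_segment()].
#' @param low,high Band edges in Hz (defaults 6 and 9).
#' @param order Butterworth order (default 4).
#' @return The filtered segment.
#' @export
bandpass_low_alpha <- function(seg, low = 6, high = 9, order = 4) {
  stopifnot(inherits(seg, "eeg_segment"))
  if (low <= 0 || high <= low)
    stop("band edges must satisfy 0 < low < high")
  if (high >= seg$fs / 2)
    stop("high edge must be below the Nyquist frequency ", seg$fs / 2, " Hz")
  bf <- signal::butter(order, c(low, high) / (seg$fs / 2), type = "pass")
  out <- t(apply(seg$data, 1, function(x) signal::filtfilt(bf, x)))
  eeg_segment(out, fs = seg$fs, channel_labels = seg$channel_labels,
              subject_id = seg$subject_id, segment_id = seg$segment_id)
}

#' Re-reference to the common average
#'
#' Subtracts, at every time point, the instantaneous mean across channels,
#' so each column of the output sums to zero.
#'
#' @param seg An [eeg_segment()].
#' @return The re-referenced segment.
#' @export
rereference_average <- function(seg) {
  stopifnot(inherits(seg, "eeg_segment"))
  if (nrow(seg$data) < 2L)
    stop("average re-referencing needs at least 2 channels")
  out <- sweep(seg$data, 2, colMeans(seg$data))
  eeg_segment(out, fs = seg$fs, channel_labels = seg$channel_labels,
              subject_id = seg$subject_id, segment_id = seg$segment_id)
}

#' Select analysis windows from a long recording
#'
#' Positional stand-in for clinical segment selection: returns `n`
#' non-overlapping windows of exact `length` whose start times are at least
#' `min_gap + length` apart. Optionally vetoes windows containing extreme
#' amplitudes.
#'
#' @param recording An [eeg_segment()] covering the full recording.
#' @param n Number of windows (default 3).
#' @param length Window length in seconds (default 20).
#' @param min_gap Minimum gap between consecutive windows in seconds
#'   (default 60).
#' @param amplitude_veto If `TRUE`, windows where any sample exceeds
#'   `veto_z` channel-wise standard deviations are skipped.
#' @param veto_z Veto threshold in z-score units.
#' @return A list of `n` segments.
#' @export
pick_segments <- function(recording, n = 3, length = 20, min_gap = 60,
                          amplitude_veto = FALSE, veto_z = 6) {
  stopifnot(inherits(recording, "eeg_segment"))
  fs <- recording$fs
  need <- n * length + (n - 1) * min_gap
  total <- n_samples(recording) / fs
  if (total < need)
    stop(sprintf("recording lasts %.1f s but %d segments of %g s with %g s gaps need at least %.1f s",
                 total, n, length, min_gap, need))
  win <- round(length * fs)
  stride <- round((length + min_gap) * fs)
  mu <- rowMeans(recording$data)
  sdv <- apply(recording$data, 1, sd)
  out <- list()
  start <- 1L
  while (length(out) < n && start + win - 1L <= n_samples(recording)) {
    block <- recording$data[, start:(start + win - 1L), drop = FALSE]
    ok <- TRUE
    if (amplitude_veto) {
      z <- abs(block - mu) / pmax(sdv, .Machine$double.eps)
      ok <- max(z) <= veto_z
    }
    if (ok) {
      out[[length(out) + 1L]] <- eeg_segment(
        block, fs = fs, channel_labels = recording$channel_labels,
        subject_id = recording$subject_id,
        segment_id = sprintf("win%d", length(out) + 1L))
      start <- start + stride
    } else {
      start <- start + win
    }
  }
  if (length(out) < n)
    stop("could not place ", n, " admissible windows in the recording")
  out
}

#' Full signal-conditioning chain
#'
#' Applies, in order: downsampling to `target_fs`, zero-phase Butterworth
#' band-pass, and common-average re-referencing. A canonical 20 s segment at
#' 250 Hz yields 5000 samples.
#'
#' @param seg An [eeg_segment()].
#' @param target_fs Target sampling rate (default 250 Hz).
#' @param band Pass band in Hz (default `c(6, 9)`, low alpha).
#' @param order Butterworth order (default 4).
#' @return The conditioned segment.
#' @export
preprocess_segment <- function(seg, target_fs = 250, band = c(6, 9),
                               order = 4) {
  seg <- downsample(seg, target_fs)
  seg <- bandpass_low_alpha(seg, band[1], band[2], order)
  rereference_average(seg)
}
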