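#' EEG segment container
#'
#' A single multichannel EEG recording segment: a channels-by-samples matrix
#' of amplitudes (arbitrary units) with its sampling rate and channel labels.
#' This is the raw input unit consumed by [preprocess_segment()] and
#' [build_network()].
#'
#' @param data Numeric matrix, channels x samples. Row names, if present,
#'   must match `channel_labels`.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector naming each row of `data`.
#' @param subject_id,segment_id Optional identifiers carried through the
#'   pipeline for provenance.
#'
#' @return An object of class `eeg_segment`.
#' @export
eeg_segment <- function(data, fs, channel_labels = rownames(data),
                        subject_id = NA_character_, segment_id = NA_character_) {
  data <- as.matrix(data)
  if (is.null(channel_labels))
    stop("channel_labels must be supplied when data has no row names")
  if (nrow(data) != length(channel_labels))
    stop("data has ", nrow(data), " rows but ", length(channel_labels),
         " channel labels")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (!all(is.finite(data)))
    stop("data contains non-finite values")
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = as.character(channel_labels),
         subject_id = subject_id, segment_id = segment_id),
    class = "eeg_segment"
  )
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> %d channels x %d samples @ %g Hz (%.3g s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (!is.na(x$subject_id) || !is.na(x$segment_id))
    cat(sprintf("  subject: %s  segment: %s\n", x$subject_id, x$segment_id))
  invisible(x)
}

#' @export
dim.eeg_segment <- function(x) dim(x$data)

n_samples <- function(seg) ncol(seg$data)
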