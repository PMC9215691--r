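#' Instantaneous phase via the Hilbert transform
#'
#' Computes the analytic signal of each (band-limited) channel by the FFT
#' method and returns its phase, wrapped to `(-pi, pi]`.
#'
#' @param seg A preprocessed [eeg_segment()].
#' @return An object of class `phase_series`: list with `phases`
#'   (channels x samples, radians), `fs` and `channel_labels`.
#' @export
instantaneous_phase <- function(seg) {
  stopifnot(inherits(seg, "eeg_segment"))
  v <- apply(seg$data, 1, sd)
  if (any(v == 0))
    stop("constant (zero-variance) channel: ",
         paste(seg$channel_labels[v == 0], collapse = ", "))
  ph <- t(apply(seg$data, 1, function(x) Arg(analytic_signal(x))))
  structure(list(phases = ph, fs = seg$fs,
                 channel_labels = seg$channel_labels),
            class = "phase_series")
}

# Analytic signal x + i*H(x) via the frequency-domain construction.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Phase-locking value and mean phase lag for one channel pair
#'
#' `plv` is the modulus of the time-averaged unit phasor of the phase
#' differences; `tau` is the argument of the summed phasor, in `(-pi, pi]`.
#'
#' @param phase_i,phase_j Instantaneous phase vectors of equal length.
#' @return List with elements `plv` (in `[0, 1]`) and `tau` (radians).
#' @export
plv_pair <- function(phase_i, phase_j) {
  if (length(phase_i) == 0L || length(phase_j) == 0L)
    stop("phase series must be non-empty")
  if (length(phase_i) != length(phase_j))
    stop("phase series must have equal length")
  s <- sum(exp(1i * (phase_i - phase_j)))
  list(plv = Mod(s) / length(phase_i), tau = Arg(s))
}

# All-pairs PLV/tau from a channels x samples phase matrix, via one complex
# cross-product. tau[i, j] = arg sum exp(i (phi_i - phi_j)).
plv_matrix <- function(phases) {
  e <- exp(1i * phases)
  s <- e %*% Conj(t(e))
  list(plv = Mod(s) / ncol(phases), tau = Arg(s))
}

#' Iterative amplitude-adjusted Fourier transform surrogate
#'
#' Generates a surrogate series whose sorted sample values equal the
#' original's exactly (the iteration ends on the amplitude-adjustment step)
#' and whose power spectrum approximates the original's.
#'
#' @param x Numeric vector, length >= 2.
#' @param n_iterations Number of IAAFT iterations (default 10).
#' @param seed Optional integer seed for the initial shuffle; if `NULL` the
#'   current RNG state is used.
#' @param trace If `TRUE`, attach the per-iteration relative spectral error
#'   as attribute `"spectral_error"`.
#' @return The surrogate series.
#' @export
iaaft_surrogate <- function(x, n_iterations = 10, seed = NULL, trace = FALSE) {
  n <- length(x)
  if (n < 2L) stop("signal must have length >= 2")
  if (!is.null(seed)) set.seed(seed)
  amp_sorted <- sort(x)
  target_mod <- Mod(fft(x))
  y <- sample(x)
  err <- numeric(n_iterations)
  for (k in seq_len(n_iterations)) {
    # impose the target amplitude spectrum, keep current phases
    f <- fft(y)
    y <- Re(fft(target_mod * exp(1i * Arg(f)), inverse = TRUE) / n)
    # restore the exact amplitude distribution by rank mapping
    y[sort.list(y, method = "radix")] <- amp_sorted
    if (trace)
      err[k] <- sqrt(sum((Mod(fft(y)) - target_mod)^2) / sum(target_mod^2))
  }
  if (trace) attr(y, "spectral_error") <- err
  y
}

# IAAFT surrogates for all channels of a segment at once (samples x channels
# in, same out). Bit-identical to calling iaaft_surrogate() per channel with
# the same seeds: only the seeded initial shuffle is random, the iterations
# are deterministic, and mvfft just batches the per-column FFTs.
iaaft_surrogate_matrix <- function(xt, n_iterations, seeds) {
  n <- nrow(xt)
  amp_sorted <- apply(xt, 2, sort)
  target_mod <- Mod(mvfft(xt))
  y <- xt
  for (c in seq_len(ncol(xt))) {
    set.seed(seeds[c])
    y[, c] <- sample(xt[, c])
  }
  for (k in seq_len(n_iterations)) {
    f <- mvfft(y)
    y <- Re(mvfft(target_mod * exp(1i * Arg(f)), inverse = TRUE) / n)
    for (c in seq_len(ncol(xt)))
      y[sort.list(y[, c], method = "radix"), c] <- amp_sorted[, c]
  }
  y
}

#' Surrogate significance decision for one PLV value
#'
#' The observed PLV is significant when it strictly exceeds at least
#' `ceiling(level * n)` of the `n` surrogate PLVs (>= 95 of 99 at the
#' default level); ties count against significance.
#'
#' @param plv_observed Observed PLV.
#' @param plv_surrogates Vector of surrogate PLVs (default length 99).
#' @param level Required exceedance fraction (default 0.95).
#' @return `TRUE` if the observed PLV passes.
#' @export
surrogate_threshold <- function(plv_observed, plv_surrogates, level = 0.95) {
  n <- length(plv_surrogates)
  if (n < 1L) stop("at least one surrogate PLV is required")
  sum(plv_observed > plv_surrogates) >= ceiling(level * n)
}

#' Functional network container
#'
#' @param weights Symmetric matrix of significant PLV values (0 where an
#'   edge was rejected), zero diagonal.
#' @param lags Matrix of mean phase lags (radians), antisymmetric where
#'   `weights > 0`.
#' @param channel_labels Channel names.
#' @param provenance Optional list (subject, segment, seed).
#' @return An object of class `functional_network`.
#' @export
functional_network <- function(weights, lags, channel_labels,
                               provenance = list()) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  stopifnot(ncol(weights) == n, all(dim(lags) == n),
            length(channel_labels) == n)
  if (max(abs(weights - t(weights))) > 1e-12)
    stop("weights must be symmetric")
  if (any(diag(weights) != 0)) stop("weights must have zero diagonal")
  if (any(weights < 0 | weights > 1)) stop("weights must lie in [0, 1]")
  dimnames(weights) <- list(channel_labels, channel_labels)
  structure(list(weights = weights, lags = lags,
                 channel_labels = as.character(channel_labels),
                 provenance = provenance),
            class = "functional_network")
}

#' @export
print.functional_network <- function(x, ...) {
  n <- nrow(x$weights)
  ne <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("<functional_network> %d nodes, %d edges (density %.2f)\n",
              n, ne, ne / (n * (n - 1) / 2)))
  invisible(x)
}

#' Build the functional network of one EEG segment
#'
#' For every channel pair the PLV and mean lag are computed from Hilbert
#' phases. An edge survives only if (a) its absolute lag exceeds the
#' volume-conduction threshold `2*pi/fs`, and (b) its PLV strictly exceeds
#' at least 95% of the PLVs obtained from IAAFT surrogate pairs. Surrogates
#' are generated per channel (one matched surrogate pair per replicate),
#' band-passed again (IAAFT does not exactly preserve band limits), and
#' their PLVs recomputed, so the null preserves each channel's amplitude
#' distribution and spectrum.
#'
#' @param seg A preprocessed (band-limited) [eeg_segment()].
#' @param n_surrogates Number of surrogate replicates (default 99).
#' @param n_iterations IAAFT iterations per surrogate (default 10).
#' @param seed Root seed; surrogate seeds derive deterministically from
#'   (seed, replicate, channel).
#' @param band,order Band-pass applied to the surrogates; must match the
#'   preprocessing of `seg`.
#' @param level Required surrogate exceedance fraction (default 0.95).
#' @return A `functional_network`.
#' @export
build_network <- function(seg, n_surrogates = 99, n_iterations = 10,
                          seed = 1L, band = c(6, 9), order = 4,
                          level = 0.95) {
  stopifnot(inherits(seg, "eeg_segment"))
  n <- nrow(seg$data)
  obs <- plv_matrix(instantaneous_phase(seg)$phases)
  tau0 <- 2 * pi / seg$fs
  exceed <- matrix(0L, n, n)
  xt <- t(seg$data)
  for (r in seq_len(n_surrogates)) {
    surr <- t(iaaft_surrogate_matrix(
      xt, n_iterations,
      seeds = vapply(seq_len(n), function(c) derive_seed(seed, r, c),
                     integer(1))))
    sseg <- eeg_segment(surr, fs = seg$fs,
                        channel_labels = seg$channel_labels)
    sseg <- bandpass_low_alpha(sseg, band[1], band[2], order)
    sp <- plv_matrix(instantaneous_phase(sseg)$phases)
    exceed <- exceed + (obs$plv > sp$plv)
  }
  keep <- (exceed >= ceiling(level * n_surrogates)) &
    (abs(obs$tau) > tau0)
  diag(keep) <- FALSE
  keep <- keep & t(keep)  # both orientations agree (tau is antisymmetric)
  w <- ifelse(keep, obs$plv, 0)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  functional_network(w, obs$tau, seg$channel_labels,
                     provenance = list(subject = seg$subject_id,
                                       segment = seg$segment_id,
                                       seed = seed))
}
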