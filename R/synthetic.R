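#' Specification for one synthetic EEG segment
#'
#' Describes a network of stochastic Kuramoto-type phase oscillators observed
#' through a cosine, the generative model used to emulate band-limited
#' resting EEG with controllable pairwise phase coupling. Ground truth for
#' the downstream phase-locking analysis is explicit: `pair_coupling[i, j]`
#' sets how strongly channels i and j are pulled into lock, and
#' `pair_lag[i, j]` is the phase by which channel i leads channel j in the
#' locked state.
#'
#' @param n_channels Number of channels (default 20, the 10-20 set).
#' @param pair_coupling Symmetric matrix of coupling strengths in `[0, 1]`
#'   with zero diagonal. Default: the spatial-neighbour template of
#'   [default_pair_coupling()].
#' @param pair_lag Antisymmetric matrix of target phase lags (radians).
#'   Default: an anterior-posterior phase gradient ([default_pair_lag()])
#'   that keeps all coupled pairs away from zero lag.
#' @param oscillator_band Frequency interval (Hz) from which each channel's
#'   natural frequency is drawn uniformly; default 6-9 Hz (low alpha).
#' @param observation_noise_sd White observation noise added to the cosine
#'   readout (amplitude units; signals have unit carrier amplitude).
#' @param phase_noise_sd Intensity of the phase diffusion (rad per sqrt
#'   second). Together with `coupling_gain` it sets how PLV grades with
#'   coupling strength.
#' @param coupling_gain Conversion from dimensionless coupling in `[0, 1]`
#'   to pull rate in rad/s. The default is strong enough that a 0.9 coupling
#'   locks any detuning within the 6-9 Hz band with a lag bias below 0.1 rad.
#' @param fs Sampling rate (Hz).
#' @param duration Segment length (seconds).
#' @param seed Integer seed; generation is bit-reproducible given the spec.
#' @param channel_labels Channel names; defaults to [channels_1020] when
#'   `n_channels` is 20.
#'
#' @return An object of class `coupling_spec`.
#' @seealso [generate_segment()], [cohort_spec()]
#' @export
coupling_spec <- function(n_channels = 20L,
                          pair_coupling = default_pair_coupling(n_channels),
                          pair_lag = default_pair_lag(n_channels),
                          oscillator_band = c(6, 9),
                          observation_noise_sd = 0.3,
                          phase_noise_sd = 6,
                          coupling_gain = 110,
                          fs = 250,
                          duration = 20,
                          seed = 1L,
                          channel_labels = NULL) {
  if (is.null(channel_labels))
    channel_labels <- if (n_channels == 20L) channels_1020 else
      sprintf("CH%02d", seq_len(n_channels))
  spec <- structure(
    list(n_channels = as.integer(n_channels), pair_coupling = pair_coupling,
         pair_lag = pair_lag, oscillator_band = oscillator_band,
         observation_noise_sd = observation_noise_sd,
         phase_noise_sd = phase_noise_sd, coupling_gain = coupling_gain,
         fs = fs, duration = duration, seed = as.integer(seed),
         channel_labels = channel_labels),
    class = "coupling_spec"
  )
  validate_coupling_spec(spec)
  spec
}

validate_coupling_spec <- function(spec) {
  n <- spec$n_channels
  pc <- spec$pair_coupling
  if (!is.matrix(pc) || !all(dim(pc) == n))
    stop("pair_coupling must be a ", n, "x", n, " matrix")
  if (max(abs(pc - t(pc))) > 1e-12)
    stop("pair_coupling must be symmetric")
  if (any(diag(pc) != 0))
    stop("pair_coupling must have zero diagonal")
  if (any(pc < 0 | pc > 1))
    stop("pair_coupling entries must lie in [0, 1]")
  pl <- spec$pair_lag
  if (!is.matrix(pl) || !all(dim(pl) == n))
    stop("pair_lag must be a ", n, "x", n, " matrix")
  if (max(abs(pl + t(pl))) > 1e-12)
    stop("pair_lag must be antisymmetric")
  b <- spec$oscillator_band
  if (length(b) != 2L || b[1] >= b[2])
    stop("oscillator_band lower edge must be below its upper edge")
  if (spec$fs <= 2 * b[2])
    stop("fs must exceed twice the oscillator_band upper edge")
  if (spec$observation_noise_sd < 0 || spec$phase_noise_sd < 0)
    stop("noise standard deviations must be non-negative")
  if (spec$duration <= 0) stop("duration must be positive")
  if (length(spec$channel_labels) != n)
    stop("channel_labels must have one entry per channel")
  invisible(spec)
}

#' Default coupling template on the 10-20 montage
#'
#' Spatially neighbouring electrodes of the 10-20 layout are coupled at a
#' common baseline strength; all other pairs are uncoupled. For channel
#' counts other than 20 a ring of nearest neighbours is used instead.
#'
#' @param n_channels Number of channels.
#' @param strength Baseline coupling for neighbouring pairs.
#' @return Symmetric `n_channels x n_channels` matrix.
#' @export
default_pair_coupling <- function(n_channels = 20L, strength = 0.35) {
  n <- as.integer(n_channels)
  m <- matrix(0, n, n)
  if (n == 20L) {
    dimnames(m) <- list(channels_1020, channels_1020)
    for (e in montage_neighbours())
      m[e[1], e[2]] <- m[e[2], e[1]] <- strength
  } else {
    for (i in seq_len(n)) {
      j <- i %% n + 1L
      m[i, j] <- m[j, i] <- strength
    }
  }
  m
}

# Neighbouring electrode pairs on the 10-20 scalp grid (rows front to back:
# FP, F, C, P, O), including inter-row links.
montage_neighbours <- function() {
  list(
    c("FP1", "FPZ"), c("FPZ", "FP2"),
    c("F7", "F3"), c("F3", "FZ"), c("FZ", "F4"), c("F4", "F8"),
    c("T3", "C3"), c("C3", "CZ"), c("CZ", "C4"), c("C4", "T4"),
    c("T5", "P3"), c("P3", "PZ"), c("PZ", "P4"), c("P4", "T6"),
    c("O1", "O2"),
    c("FP1", "F3"), c("FPZ", "FZ"), c("FP2", "F4"),
    c("FP1", "F7"), c("FP2", "F8"),
    c("F7", "T3"), c("F3", "C3"), c("FZ", "CZ"), c("F4", "C4"), c("F8", "T4"),
    c("T3", "T5"), c("C3", "P3"), c("CZ", "PZ"), c("C4", "P4"), c("T4", "T6"),
    c("T5", "O1"), c("P3", "O1"), c("PZ", "O1"),
    c("PZ", "O2"), c("P4", "O2"), c("T6", "O2")
  )
}

#' Default pairwise lag template
#'
#' Lags derive from a per-channel phase potential laid out as a travelling
#' wave: channels are ranked front-to-back along the scalp and assigned
#' phases evenly spaced over the full circle. Every coupled pair then has a
#' consistent target lag of at least `2*pi/n` (well above the
#' volume-conduction rejection threshold `2*pi/fs`), and the coherent
#' component cancels in the channel mean, so common-average re-referencing
#' does not leak a synchronous field into uncoupled channels.
#'
#' @param n_channels Number of channels.
#' @param channel_labels Optional labels; when all belong to the standard
#'   10-20 set the scalp (anterior-to-posterior) ordering is used, otherwise
#'   the given order.
#' @return Antisymmetric matrix of target lags `u_i - u_j` (radians).
#' @export
default_pair_lag <- function(n_channels = 20L, channel_labels = NULL) {
  n <- as.integer(n_channels)
  if (is.null(channel_labels) && n == 20L) channel_labels <- channels_1020
  if (!is.null(channel_labels) && all(channel_labels %in% channels_1020)) {
    scalp_order <- c("FP1", "FPZ", "FP2", "F7", "F3", "FZ", "F4", "F8",
                     "T3", "C3", "CZ", "C4", "T4",
                     "T5", "P3", "PZ", "P4", "T6", "O1", "O2")
    u <- 2 * pi * (match(channel_labels, scalp_order) - 1) /
      length(scalp_order)
    # re-space evenly over the circle for partial montages
    u <- 2 * pi * (rank(u) - 1) / n
  } else {
    u <- 2 * pi * (seq_len(n) - 1) / n
  }
  m <- outer(u, u, "-")
  dimnames(m) <- NULL
  m
}

#' Posterior 8-channel montage
#'
#' Central-posterior subset of the 10-20 montage used for reduced-scale
#' cohort experiments (it keeps both occipital channels).
#'
#' @format Character vector of length 8.
#' @export
channels_posterior <- c("CZ", "O1", "O2", "P3", "P4", "PZ", "T5", "T6")

#' Cohort baseline coupling: coherent backbone with a detached right occiput
#'
#' The cohort generator's baseline network: every channel except O2 belongs
#' to a uniformly coupled coherent core (`backbone_strength`), on which
#' seizure-like dynamics can always be calibrated, while the right occipital
#' channel O2 is detached (coupling `detached_strength`, default 0), so its
#' connections are rejected downstream. The group-A occipital boost then
#' integrates O2 into the coherent core and strengthens the occipital rows,
#' which is the manipulation the pipeline is meant to detect: the node
#' ictogenicity of a detached channel sits clearly below that of an
#' integrated one.
#'
#' @param channel_labels Montage (must contain O1 and O2).
#' @param backbone_strength Coupling among core pairs (default 0.3).
#' @param detached_strength Baseline coupling of O2 to everything
#'   (default 0: detached).
#' @return Symmetric coupling matrix (dimnames = channel labels).
#' @export
cohort_baseline_coupling <- function(channel_labels = channels_1020,
                                     backbone_strength = 0.3,
                                     detached_strength = 0) {
  n <- length(channel_labels)
  if (!all(c("O1", "O2") %in% channel_labels))
    stop("montage must contain O1 and O2")
  m <- matrix(backbone_strength, n, n,
              dimnames = list(channel_labels, channel_labels))
  det <- channel_labels == "O2"
  m[det, ] <- detached_strength
  m[, det] <- detached_strength
  diag(m) <- 0
  m
}

#' Generate one synthetic EEG segment
#'
#' Integrates the stochastic phase-oscillator network described by `spec`
#' (Euler-Maruyama, four substeps per output sample) and observes each
#' channel as `cos(phase)` plus white observation noise.
#'
#' @param spec A [coupling_spec()].
#' @param subject_id,segment_id Optional provenance identifiers.
#' @return An [eeg_segment()] of `spec$n_channels` x `spec$fs * spec$duration`
#'   samples. Bit-identical across calls with the same spec (including seed).
#' @export
generate_segment <- function(spec, subject_id = NA_character_,
                             segment_id = NA_character_) {
  validate_coupling_spec(spec)
  n <- spec$n_channels
  nt <- round(spec$fs * spec$duration)
  substeps <- 4L
  dt <- 1 / (spec$fs * substeps)
  set.seed(spec$seed)
  omega <- 2 * pi * runif(n, spec$oscillator_band[1], spec$oscillator_band[2])
  theta0 <- runif(n, -pi, pi)
  gain <- spec$coupling_gain * spec$pair_coupling
  phases <- kuramoto_sim_cpp(gain, spec$pair_lag, omega, spec$phase_noise_sd,
                             dt, nt * substeps, theta0)
  keep <- seq(substeps, nt * substeps, by = substeps)
  x <- cos(phases[, keep, drop = FALSE])
  if (spec$observation_noise_sd > 0)
    x <- x + matrix(rnorm(n * nt, sd = spec$observation_noise_sd), n, nt)
  eeg_segment(x, fs = spec$fs, channel_labels = spec$channel_labels,
              subject_id = subject_id, segment_id = segment_id)
}

#' Specification for a two-group synthetic cohort
#'
#' Describes a cohort in which group A ("PPR-like") receives an additive
#' boost to all couplings involving the occipital channels O1 and O2, while
#' group B keeps the baseline structure (by default a coherent non-occipital
#' backbone with a detached occiput, see [cohort_baseline_coupling()]).
#' Between-subject and between-segment variability enter as relative
#' (multiplicative truncated-normal) jitter on the coupling strengths,
#' clipped to `[0, 1]`; lags are left untouched so the phase-lag ground
#' truth is stable.
#'
#' @param n_group_a,n_group_b Subjects per group (defaults 26 and 20, the
#'   photosensitive-cohort sizes the generator emulates).
#' @param segments_per_subject Segments per subject (default 3).
#' @param baseline A [coupling_spec()] shared by both groups.
#' @param occipital_boost Additive coupling increment applied to the O1/O2
#'   rows and columns in group A (default 0.4).
#' @param subject_sd,segment_sd Relative jitter scales for between-subject
#'   and between-segment coupling variability.
#' @param seed Integer root seed; all per-subject/segment seeds derive from
#'   it deterministically.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_group_a = 26L, n_group_b = 20L,
                        segments_per_subject = 3L,
                        baseline = coupling_spec(
                          pair_coupling = unname(cohort_baseline_coupling())),
                        occipital_boost = 0.4,
                        subject_sd = 0.05, segment_sd = 0.03,
                        seed = 1L) {
  if (segments_per_subject < 1L)
    stop("segments_per_subject must be at least 1")
  if (n_group_a < 1L || n_group_b < 1L)
    stop("both groups need at least one subject")
  if (occipital_boost < 0) stop("occipital_boost must be non-negative")
  validate_coupling_spec(baseline)
  structure(
    list(n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
         segments_per_subject = as.integer(segments_per_subject),
         baseline = baseline, occipital_boost = occipital_boost,
         subject_sd = subject_sd, segment_sd = segment_sd,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a two-group synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `eeg_cohort`: a list with `subjects` (each a
#'   list of `subject_id`, `group` in `{"PPR", "nonPPR"}`, `segments` and the
#'   ground-truth coupling matrix per segment in `truth`) and the `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  base <- spec$baseline
  labels <- base$channel_labels
  occ <- which(labels %in% c("O1", "O2"))
  groups <- c(rep("PPR", spec$n_group_a), rep("nonPPR", spec$n_group_b))
  ids <- c(sprintf("PPR%02d", seq_len(spec$n_group_a)),
           sprintf("NONPPR%02d", seq_len(spec$n_group_b)))
  structural <- base$pair_coupling > 0
  subjects <- vector("list", length(ids))
  for (s in seq_along(ids)) {
    pc_group <- base$pair_coupling
    if (groups[s] == "PPR" && spec$occipital_boost > 0 && length(occ)) {
      pc_group[occ, ] <- pc_group[occ, ] + spec$occipital_boost
      pc_group[, occ] <- base$pair_coupling[, occ] + spec$occipital_boost
      pc_group[occ, occ] <- base$pair_coupling[occ, occ] + spec$occipital_boost
      diag(pc_group) <- 0
      pc_group <- pmin(pc_group, 1)
    }
    active <- structural | pc_group > 0
    set.seed(derive_seed(spec$seed, 11L, s))
    pc_subj <- jitter_coupling(pc_group, active, spec$subject_sd)
    segs <- vector("list", spec$segments_per_subject)
    truth <- vector("list", spec$segments_per_subject)
    for (k in seq_len(spec$segments_per_subject)) {
      set.seed(derive_seed(spec$seed, 13L, s, k))
      pc_seg <- jitter_coupling(pc_subj, active, spec$segment_sd)
      seg_spec <- base
      seg_spec$pair_coupling <- pc_seg
      seg_spec$seed <- derive_seed(spec$seed, 17L, s, k)
      segs[[k]] <- generate_segment(seg_spec, subject_id = ids[s],
                                    segment_id = sprintf("seg%d", k))
      truth[[k]] <- pc_seg
    }
    subjects[[s]] <- list(subject_id = ids[s], group = groups[s],
                          segments = segs, truth = truth)
  }
  structure(list(subjects = subjects, spec = spec), class = "eeg_cohort")
}

# Relative symmetric jitter on the couplings: each active pair's strength is
# scaled by a truncated-normal factor 1 + N(0, sd), so weak couplings stay
# weak and strong ones vary proportionally. Clipped to [0, 1]; uses the
# current RNG state.
jitter_coupling <- function(pc, active, sd) {
  if (sd <= 0) return(pc)
  n <- nrow(pc)
  f <- matrix(0, n, n)
  upper <- upper.tri(pc) & active
  f[upper] <- pmax(1 + rnorm(sum(upper), sd = sd), 0)
  f <- f + t(f)
  f[!active | row(f) == col(f)] <- 1
  out <- pmin(pmax(pc * f, 0), 1)
  diag(out) <- 0
  out
}

#' @export
print.eeg_cohort <- function(x, ...) {
  g <- vapply(x$subjects, function(s) s$group, character(1))
  cat(sprintf("<eeg_cohort> %d subjects (%d PPR, %d nonPPR), %d segment(s) each\n",
              length(g), sum(g == "PPR"), sum(g == "nonPPR"),
              x$spec$segments_per_subject))
  invisible(x)
}

#' Reduced-scale cohort specification on the posterior montage
#'
#' Convenience constructor for cohort experiments at reduced problem size:
#' the 10-channel posterior montage ([channels_posterior]), shorter segments,
#' and the same backbone-plus-detached-occiput baseline as the full design.
#'
#' @param n_group_a,n_group_b Subjects per group.
#' @param occipital_boost Additive occipital coupling increment in group A.
#' @param segments_per_subject Segments per subject (default 3).
#' @param duration Segment length in seconds (default 4).
#' @param seed Root seed.
#' @return A [cohort_spec()].
#' @export
reduced_cohort_spec <- function(n_group_a = 13L, n_group_b = 10L,
                                occipital_boost = 0.4,
                                segments_per_subject = 3L,
                                duration = 4, seed = 1L) {
  labels <- channels_posterior
  base <- coupling_spec(
    n_channels = length(labels),
    pair_coupling = unname(cohort_baseline_coupling(labels)),
    pair_lag = default_pair_lag(length(labels), labels),
    duration = duration,
    channel_labels = labels)
  cohort_spec(n_group_a = n_group_a, n_group_b = n_group_b,
              segments_per_subject = segments_per_subject,
              baseline = base, occipital_boost = occipital_boost,
              seed = seed)
}
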