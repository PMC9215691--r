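# Shared fixture builders. All simulated inputs are generated here in code,
# at reduced problem sizes chosen for test runtime; the scientific constants
# (I0, sigma, band, surrogate rule) stay at their canonical values.

# A pure tone segment on n channels (same tone everywhere unless phases given).
tone_segment <- function(freq = 7.5, fs = 250, duration = 4, n_channels = 2,
                         phases = rep(0, n_channels), amplitude = 1) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  data <- t(vapply(phases, function(ph) amplitude * cos(2 * pi * freq * t + ph),
                   numeric(length(t))))
  eeg_segment(data, fs = fs,
              channel_labels = sprintf("CH%02d", seq_len(n_channels)))
}

# White-noise segment.
noise_segment <- function(n_channels = 4, fs = 250, duration = 4, seed = 1) {
  set.seed(seed)
  eeg_segment(matrix(rnorm(n_channels * fs * duration), n_channels),
              fs = fs, channel_labels = sprintf("CH%02d", seq_len(n_channels)))
}

# Coupling spec with a single coupled pair, defaults otherwise. On the full
# montage the pair is O1-O2; on smaller montages, the first two channels.
pair_spec <- function(coupling = 0.9, lag = pi / 4, n_channels = 20,
                      duration = 20, seed = 1, ...) {
  pc <- matrix(0, n_channels, n_channels)
  pl <- matrix(0, n_channels, n_channels)
  if (n_channels == 20) {
    i <- match("O1", channels_1020)
    j <- match("O2", channels_1020)
  } else {
    i <- 1L; j <- 2L
  }
  pc[i, j] <- pc[j, i] <- coupling
  pl[i, j] <- lag
  pl[j, i] <- -lag
  coupling_spec(n_channels = n_channels, pair_coupling = pc, pair_lag = pl,
                duration = duration, seed = seed, ...)
}

# Simple phase unwrapping for test oracles.
unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}

# Reduced-scale theta parameters for fast simulation tests.
fast_theta <- function(K = 1, n_steps = 2e4, noise_sd = 0.6, seed = 1, ...) {
  theta_params(K = K, n_steps = n_steps, noise_sd = noise_sd, seed = seed, ...)
}

# Small deterministic functional network for ictogenicity tests.
toy_network <- function(n = 6, weights = NULL) {
  if (is.null(weights)) {
    weights <- matrix(0.4, n, n)
    diag(weights) <- 0
  }
  n <- nrow(weights)
  functional_network(weights, matrix(0.5, n, n) * upper.tri(weights) -
                       matrix(0.5, n, n) * lower.tri(weights),
                     sprintf("node%d", seq_len(n)))
}

# Exhaustive-enumeration oracle for the rank-sum right-tail p-value:
# distribution of the group-1 rank sum over all choose(n, n1) assignments.
enumerate_ranksum_p <- function(W, n1, n2, tail = "right") {
  combs <- utils::combn(n1 + n2, n1)
  Ws <- colSums(combs)
  if (tail == "right") mean(Ws >= W)
  else min(1, 2 * min(mean(Ws >= W), mean(Ws <= W)))
}
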