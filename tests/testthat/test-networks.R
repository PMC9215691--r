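test_that("instantaneous phase tracks a pure tone", {
  seg <- tone_segment(freq = 7, fs = 250, duration = 8, n_channels = 2,
                      phases = c(0, -pi / 2)) # cos and sin of the same tone
  ph <- instantaneous_phase(seg)
  mid <- 200:1800
  # unwrapped slope ~ 2*pi*7 rad/s within 1%
  slope <- mean(diff(unwrap_phase(ph$phases[1, mid]))) * seg$fs
  expect_lt(abs(slope - 2 * pi * 7) / (2 * pi * 7), 0.01)
  # quadrature pair: constant difference pi/2
  d <- ph$phases[1, mid] - ph$phases[2, mid]
  d <- atan2(sin(d), cos(d))
  expect_lt(max(abs(d - pi / 2)), 0.02)
  expect_true(all(ph$phases > -pi & ph$phases <= pi + 1e-12))
  flat <- eeg_segment(matrix(c(1, 2), 2, 100) * 0 + c(1, 1), 250, c("a", "b"))
  expect_error(instantaneous_phase(flat), "constant")
})

test_that("plv_pair matches its closed forms and the Rayleigh null", {
  ph <- runif(1000, -pi, pi)
  same <- plv_pair(ph, ph)
  expect_equal(same$plv, 1)
  expect_equal(same$tau, 0)
  off <- plv_pair(ph + pi / 2, ph)
  expect_equal(off$plv, 1)
  expect_equal(off$tau, pi / 2)
  # independent phases: E[PLV] ~ sqrt(pi)/(2*sqrt(Nt))
  set.seed(21)
  nt <- 5000
  null_plv <- vapply(1:200, function(i)
    plv_pair(runif(nt, -pi, pi), runif(nt, -pi, pi))$plv, numeric(1))
  expect_lt(abs(mean(null_plv) - sqrt(pi) / (2 * sqrt(nt))), 0.002)
  expect_error(plv_pair(numeric(0), numeric(0)), "non-empty")
})

test_that("IAAFT surrogates preserve amplitudes exactly and spectra approximately", {
  set.seed(31)
  x <- as.numeric(arima.sim(list(ar = 0.8), 1024))
  s <- iaaft_surrogate(x, seed = 5, trace = TRUE)
  expect_identical(sort(s), sort(x))
  err <- attr(s, "spectral_error")
  expect_length(err, 10)
  expect_true(all(diff(err) <= 1e-8)) # non-increasing mismatch
  # lag-1 autocorrelation approximately preserved for AR(1)
  ac <- function(v) cor(v[-1], v[-length(v)])
  acs <- vapply(1:20, function(k)
    ac(iaaft_surrogate(x, seed = 100 + k)), numeric(1))
  expect_lt(abs(mean(acs) - ac(x)) / abs(ac(x)), 0.1)
  # deterministic given seed
  expect_identical(iaaft_surrogate(x, seed = 9), iaaft_surrogate(x, seed = 9))
  expect_error(iaaft_surrogate(1), "length")
})

test_that("surrogate threshold implements strict 95% exceedance", {
  surr <- seq(0.01, 0.99, length.out = 99)
  expect_true(surrogate_threshold(1, surr))
  expect_false(surrogate_threshold(min(surr), surr))
  # exceeding exactly 94 of 99 fails; exactly 95 passes
  expect_false(surrogate_threshold(surr[95] - 1e-9, surr)) # > 94 values
  expect_true(surrogate_threshold(surr[95] + 1e-9, surr))  # > 95 values
  # ties count against significance
  expect_false(surrogate_threshold(0.5, rep(0.5, 99)))
})

test_that("duplicated channels are rejected by the zero-lag rule", {
  set.seed(41)
  base <- generate_segment(pair_spec(n_channels = 4, duration = 8, seed = 2))
  dup <- eeg_segment(rbind(base$data[1, ], base$data[1, ], base$data[3:4, ]),
                     fs = base$fs, channel_labels = c("a", "b", "c", "d"))
  dup <- preprocess_segment(dup)
  net <- build_network(dup, n_surrogates = 19, seed = 3)
  expect_equal(net$weights[1, 2], 0) # PLV = 1 but tau = 0
})

test_that("build_network keeps strong coupled pairs and respects invariants", {
  seg <- preprocess_segment(generate_segment(
    pair_spec(coupling = 0.9, lag = pi / 4, n_channels = 6, duration = 8,
              seed = 5)))
  net <- build_network(seg, n_surrogates = 99, seed = 7)
  expect_gt(net$weights[1, 2], 0.8)
  w <- net$weights
  expect_identical(w, t(w))
  expect_true(all(diag(w) == 0))
  expect_true(all(w >= 0 & w <= 1))
  surviving <- which(w > 0, arr.ind = TRUE)
  expect_true(all(abs(net$lags[surviving]) > 2 * pi / seg$fs))
})

test_that("channel order permutation permutes the network consistently", {
  seg <- preprocess_segment(generate_segment(
    pair_spec(n_channels = 5, duration = 6, seed = 8)))
  net <- build_network(seg, n_surrogates = 19, seed = 11)
  perm <- c(3, 5, 1, 2, 4)
  seg_p <- eeg_segment(seg$data[perm, ], seg$fs,
                       channel_labels = seg$channel_labels[perm])
  # per-channel surrogate seeds follow the channel position, so re-derive
  # them per label through the same root seed by permuting afterwards
  net_p <- build_network(seg_p, n_surrogates = 19, seed = 11)
  # strong structure (the coupled pair) must map to the same labels
  pair <- which(net$weights == max(net$weights), arr.ind = TRUE)[1, ]
  labs <- rownames(net$weights)[pair]
  expect_equal(sort(labs), sort(c("CH01", "CH02")))
  pair_p <- which(net_p$weights == max(net_p$weights), arr.ind = TRUE)[1, ]
  expect_equal(sort(rownames(net_p$weights)[pair_p]), sort(labs))
})

test_that("functional networks serialize and round-trip", {
  dir <- withr::local_tempdir()
  w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 0.7
  lags <- matrix(0, 3, 3); lags[1, 2] <- 0.4; lags[2, 1] <- -0.4
  net <- functional_network(w, lags, c("O1", "O2", "CZ"),
                            provenance = list(subject = "s1"))
  write_network(net, file.path(dir, "net"))
  back <- read_network(file.path(dir, "net"))
  expect_equal(back$weights, net$weights)
  expect_equal(back$lags, net$lags, tolerance = 1e-12)
  expect_equal(back$channel_labels, net$channel_labels)
})
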