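test_that("coupling_spec enforces its invariants", {
  expect_error(coupling_spec(pair_coupling = matrix(0.5, 3, 3)), "20x20")
  pc <- matrix(0, 4, 4); pc[1, 2] <- 0.5 # asymmetric
  expect_error(coupling_spec(n_channels = 4, pair_coupling = pc,
                             pair_lag = matrix(0, 4, 4)), "symmetric")
  pc2 <- matrix(2, 4, 4); diag(pc2) <- 0
  expect_error(coupling_spec(n_channels = 4, pair_coupling = pc2,
                             pair_lag = matrix(0, 4, 4)), "\\[0, 1\\]")
  expect_error(coupling_spec(oscillator_band = c(9, 6)), "band")
  expect_error(coupling_spec(fs = 15), "fs must exceed")
  lag <- matrix(1, 4, 4) # not antisymmetric
  pc3 <- matrix(0, 4, 4)
  expect_error(coupling_spec(n_channels = 4, pair_coupling = pc3,
                             pair_lag = lag), "antisymmetric")
})

test_that("generation is bit-reproducible from the seed", {
  spec <- pair_spec(duration = 2, seed = 11)
  a <- generate_segment(spec)
  b <- generate_segment(spec)
  expect_identical(a$data, b$data)
  spec2 <- pair_spec(duration = 2, seed = 12)
  expect_false(identical(a$data, generate_segment(spec2)$data))
  expect_equal(dim(a$data), c(20L, 500L))
})

test_that("a strongly coupled pair is recovered with its imposed lag", {
  # coupling 0.9, lag pi/4 between O1 and O2, all other pairs uncoupled
  plvs <- c(); taus <- c()
  for (s in 1:3) {
    seg <- preprocess_segment(generate_segment(pair_spec(seed = s)))
    ph <- instantaneous_phase(seg)$phases
    i <- match("O1", channels_1020); j <- match("O2", channels_1020)
    r <- plv_pair(ph[i, ], ph[j, ])
    plvs <- c(plvs, r$plv); taus <- c(taus, r$tau)
  }
  expect_true(all(plvs > 0.8))
  expect_lt(abs(mean(taus) - pi / 4), 0.1)
})

test_that("expected PLV is monotone in coupling strength", {
  # band-pass only: with very few channels the common-average reference
  # would inject a 1/n common component that masks the coupling effect
  mean_plv <- function(coupling) {
    mean(vapply(1:6, function(s) {
      seg <- bandpass_low_alpha(generate_segment(
        pair_spec(coupling = coupling, n_channels = 4, duration = 8,
                  seed = 100 + s)))
      ph <- instantaneous_phase(seg)$phases
      plv_pair(ph[1, ], ph[2, ])$plv
    }, numeric(1)))
  }
  curve <- vapply(c(0, 0.45, 0.9), mean_plv, numeric(1))
  expect_true(all(diff(curve) > 0))
  expect_lt(curve[1], 0.25)
  expect_gt(curve[3], 0.8)
})

test_that("cohorts have the requested structure and ground truth", {
  spec <- reduced_cohort_spec(n_group_a = 3, n_group_b = 2, duration = 2,
                              seed = 9)
  coh <- generate_cohort(spec)
  expect_length(coh$subjects, 5)
  groups <- vapply(coh$subjects, `[[`, character(1), "group")
  expect_equal(sum(groups == "PPR"), 3)
  expect_equal(sum(groups == "nonPPR"), 2)
  for (subj in coh$subjects) {
    expect_length(subj$segments, 3)
    expect_length(subj$truth, 3)
    for (tr in subj$truth) {
      expect_true(all(tr >= 0 & tr <= 1))
      expect_equal(tr, t(tr))
    }
  }
  # occipital boost applied only in group A: O2 detached in group B
  labels <- coh$spec$baseline$channel_labels
  o2 <- match("O2", labels)
  tr_a <- coh$subjects[[1]]$truth[[1]]
  tr_b <- coh$subjects[[4]]$truth[[1]]
  expect_gt(min(tr_a[o2, -o2]), 0.2)
  expect_equal(unname(tr_b[o2, ]), rep(0, length(labels)))
  # determinism
  coh2 <- generate_cohort(spec)
  expect_identical(coh$subjects[[2]]$segments[[3]]$data,
                   coh2$subjects[[2]]$segments[[3]]$data)
})

test_that("fixture files round-trip signals and metadata", {
  dir <- withr::local_tempdir()
  spec <- reduced_cohort_spec(n_group_a = 2, n_group_b = 1,
                              segments_per_subject = 2, duration = 1, seed = 3)
  coh <- generate_cohort(spec)
  write_fixture(coh, dir)
  back <- read_fixture(dir)
  expect_length(back$subjects, 3)
  for (k in seq_along(back$subjects)) {
    orig <- coh$subjects[[k]]; rt <- back$subjects[[k]]
    expect_equal(rt$group, orig$group)
    for (j in seq_along(orig$segments)) {
      expect_equal(rt$segments[[j]]$data, orig$segments[[j]]$data,
                   tolerance = 1e-6)
      expect_equal(rt$segments[[j]]$fs, orig$segments[[j]]$fs)
      expect_equal(rt$segments[[j]]$channel_labels,
                   orig$segments[[j]]$channel_labels)
    }
  }
})

test_that("fixture reader reports missing files and manifests by name", {
  dir <- withr::local_tempdir()
  expect_error(read_fixture(dir), "manifest not found")
  spec <- reduced_cohort_spec(n_group_a = 1, n_group_b = 1,
                              segments_per_subject = 1, duration = 1, seed = 4)
  coh <- generate_cohort(spec)
  write_fixture(coh, dir)
  removed <- list.files(dir, pattern = "PPR01")[1]
  file.remove(file.path(dir, removed))
  expect_error(read_fixture(dir), removed, fixed = TRUE)
})

test_that("an empty cohort writes an empty manifest without crashing", {
  dir <- withr::local_tempdir()
  write_fixture(list(subjects = list()), dir)
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(manifest), 0)
  back <- read_fixture(dir)
  expect_length(back$subjects, 0)
})
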