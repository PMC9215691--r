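test_that("ranksum reproduces published one-sided statistics from raw-data conventions", {
  # Construct samples with a known rank sum: ranks of group 1 fixed.
  set.seed(1)
  x <- c(10, 20, 30)
  y <- c(5, 15, 25, 35)
  rs <- ranksum(x, y, tail = "right", exact = FALSE)
  expect_equal(rs$W, sum(rank(c(x, y))[1:3]))
  expect_equal(rs$U_mw, rs$W - 3 * 4 / 2)
  mu <- 3 * 8 / 2
  sg <- sqrt(3 * 4 * 8 / 12)
  expect_equal(rs$z, (rs$W - mu - 0.5) / sg)
})

test_that("exact small-sample mode matches exhaustive enumeration", {
  x <- c(1, 2); y <- c(3, 4)
  rs <- ranksum(x, y, tail = "right")
  expect_equal(rs$method, "exact")
  # P(W <= 3) = 1/6 by enumeration; W = 3 here so the left tail is 1/6,
  # and the right tail is P(W >= 3) = 1.
  expect_equal(enumerate_ranksum_p(3, 2, 2, "right"), 1)
  expect_equal(rs$p, 1)
  # reversed samples put group 1 on top
  rs2 <- ranksum(y, x, tail = "right")
  expect_equal(rs2$p, 1 / 6)
  # cross-check against the independent base implementation
  wt <- wilcox.test(y, x, alternative = "greater", exact = TRUE)
  expect_equal(rs2$p, unname(wt$p.value))
})

test_that("normal approximation agrees with enumeration away from tiny groups", {
  for (n1 in 3:5) for (n2 in 3:(10 - n1)) {
    if (n2 < 3) next
    combs <- utils::combn(n1 + n2, n1)
    Ws <- colSums(combs)
    for (W in unique(Ws)) {
      p_norm <- ranksum_from_summary(W, n1, n2, tail = "right")$p
      expect_lt(abs(p_norm - mean(Ws >= W)), 0.02)
    }
  }
})

test_that("ranksum_from_summary reproduces the printed group statistics", {
  # one-sided tests, n1 = 26 PPR vs n2 = 20 non-PPR
  bni <- ranksum_from_summary(556, 26, 20, tail = "right")
  expect_equal(round(bni$z, 2), -1.23)
  expect_equal(round(bni$p, 2), 0.89)
  o2 <- ranksum_from_summary(724, 26, 20, tail = "right")
  expect_equal(round(o2$z, 2), 2.49)
  o1 <- ranksum_from_summary(652, 26, 20, tail = "right")
  expect_equal(round(o1$z, 2), 0.9)
  corrected <- holm(c(o1$p, o2$p))
  expect_equal(round(corrected[2], 3), 0.013)
  expect_equal(round(corrected[1], 2), 0.18)
  # two-sided node scan rows
  c4 <- ranksum_from_summary(568, 26, 20, tail = "two-sided")
  expect_equal(round(c4$z, 2), -0.94)
  expect_equal(round(c4$p, 2), 0.35)
  t4 <- ranksum_from_summary(689, 26, 20, tail = "two-sided")
  expect_equal(round(t4$z, 2), 1.72)
  # degenerate centre: z = 0, p = 1
  mid <- ranksum_from_summary(611, 26, 20, tail = "two-sided")
  expect_equal(mid$z, 0)
  expect_equal(mid$p, 1)
  expect_error(ranksum_from_summary(100, 26, 20), "infeasible")
})

test_that("holm correction matches the step-down definition", {
  expect_equal(holm(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm(0.03), 0.03)
  # order preserved, capped at 1
  p <- c(0.9, 0.001, 0.04)
  h <- holm(p)
  expect_equal(order(h), order(p))
  expect_true(all(h <= 1) && all(h >= p))
  expect_error(holm(c(0.5, 1.2)), "0, 1")
})

test_that("bootstrap median difference recovers known shifts and is seeded", {
  set.seed(10)
  y <- rnorm(20)
  x <- y[1:16] + 5
  es <- bootstrap_median_diff(x, y, n_boot = 500, seed = 3)
  expect_equal(es$median_diff, median(x) - median(y))
  expect_true(es$ci_low <= es$median_diff && es$median_diff <= es$ci_high)
  es2 <- bootstrap_median_diff(x, y, n_boot = 500, seed = 3)
  expect_identical(es, es2)
  same <- bootstrap_median_diff(y, y, n_boot = 500, seed = 4)
  expect_equal(same$median_diff, 0)
  expect_true(same$ci_low <= 0 && 0 <= same$ci_high)
})

test_that("bootstrap CI approximately covers the true median difference", {
  # normal(1, 1) n = 26 vs normal(0, 1) n = 20; true difference 1
  hits <- 0
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    set.seed(7000 + r)
    x <- rnorm(26, 1)
    y <- rnorm(20, 0)
    es <- bootstrap_median_diff(x, y, n_boot = 400, seed = r)
    if (es$ci_low <= 1 && 1 <= es$ci_high) hits <- hits + 1
  }
  # 95% nominal; allow generous Monte-Carlo slack at 400 resamples
  expect_gt(hits / n_rep, 0.85)
})

test_that("AUC follows the Mann-Whitney identity and matches a naive count", {
  set.seed(2)
  scores <- rnorm(30)
  labels <- rep(c(TRUE, FALSE), c(14, 16))
  m <- roc_metrics(scores, labels)
  pos <- scores[labels]; neg <- scores[!labels]
  naive <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  expect_equal(m$auc, naive)
  # cross-check against pROC (fixing the direction convention)
  skip_if_not_installed("pROC")
  expect_equal(m$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              levels = c(FALSE, TRUE),
                                              direction = "<"))))
})

test_that("roc_metrics handles separation, null, and the printed worked example", {
  perfect <- roc_metrics(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  set.seed(5)
  null <- roc_metrics(rnorm(2000), rep(c(TRUE, FALSE), 1000))
  expect_lt(abs(null$auc - 0.5), 0.05)
  # published W = 724 at n1 = 26, n2 = 20: AUC = (724 - 351)/520
  expect_equal(round((724 - 26 * 27 / 2) / (26 * 20), 2), 0.72)
  expect_error(roc_metrics(1:5, rep(TRUE, 5)), "both classes")
})

test_that("relative band power matches flat- and line-spectrum oracles", {
  seg <- tone_segment(freq = 8, fs = 250, duration = 8, n_channels = 2)
  seg$data <- seg$data + 0.01 * matrix(rnorm(length(seg$data)), 2)
  rp <- relative_band_power(seg, band = c(6, 9), channel = 1)
  expect_gte(rp, 0.95)
  expect_lte(rp, 1)
  # white noise: relative power ~ bandwidth ratio 3/44
  set.seed(8)
  wn <- noise_segment(n_channels = 1, fs = 250, duration = 60)
  rpw <- relative_band_power(wn, band = c(6, 9), channel = 1)
  expect_lt(abs(rpw - 3 / 44), 0.02)
  expect_error(relative_band_power(seg, band = c(6, 9), channel = "O9"),
               "unknown channel")
  expect_error(relative_band_power(seg, band = c(120, 130), channel = 1),
               "Nyquist")
})

test_that("node strength doubles the row sum and ignores relabeling", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 0.5
  net <- functional_network(w, matrix(0, 4, 4), c("O1", "O2", "C3", "C4"))
  expect_equal(node_strength(net, "O1"), 1)
  expect_equal(node_strength(net, "C3"), 0)
  net2 <- functional_network(w, matrix(0, 4, 4), c("O1", "O2", "X", "Y"))
  expect_equal(node_strength(net2, "O1"), 1)
  expect_error(node_strength(net, "PZ"), "unknown channel")
})
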