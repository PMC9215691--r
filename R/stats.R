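#' Rank-sum (Mann-Whitney) test with the reporting conventions of the
#' pipeline
#'
#' The reported statistic `W` is the rank sum of the first sample (mid-ranks
#' under ties); `U_mw = W - n1(n1+1)/2` is the classical Mann-Whitney U. The
#' z score uses the continuity-corrected normal approximation with
#' tie-corrected variance: right tail `z = (W - mu - 0.5)/sigma`; two-sided
#' `z = (W - mu - 0.5*sign(W - mu))/sigma`, with `mu = n1(n1+n2+1)/2`. For
#' small tie-free samples (`n1 + n2 <= exact_limit`) the p-value comes from
#' the exact distribution of U instead of the normal approximation; the z
#' score is always reported from the normal-approximation formula.
#'
#' @param x,y Numeric samples (group 1 and group 2).
#' @param tail `"right"` (is group 1 larger?) or `"two-sided"`.
#' @param exact `TRUE`/`FALSE` to force the p-value mode, or `NULL` (default)
#'   to use the exact distribution when `n1 + n2 <= exact_limit` and there
#'   are no ties.
#' @param exact_limit Sample-size bound for the automatic exact mode
#'   (default 20).
#' @return An object of class `ranksum_test`: list with `W`, `U_mw`, `z`,
#'   `p`, `n1`, `n2`, `tail`, `method`.
#' @export
ranksum <- function(x, y, tail = c("right", "two-sided"), exact = NULL,
                    exact_limit = 20L) {
  tail <- match.arg(tail)
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  ties <- any(duplicated(c(x, y)))
  if (is.null(exact)) exact <- !ties && n <= exact_limit
  if (exact && ties) {
    warning("ties present; falling back to the normal approximation")
    exact <- FALSE
  }
  mu <- n1 * (n + 1) / 2
  tie_tab <- table(r)
  sigma <- sqrt(n1 * n2 / 12 *
                  ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1))))
  z <- ranksum_z(W, mu, sigma, tail)
  U <- W - n1 * (n1 + 1) / 2
  if (exact) {
    p <- switch(tail,
      "right" = 1 - pwilcox(U - 1, n1, n2),
      "two-sided" = min(1, 2 * min(pwilcox(U, n1, n2),
                                   1 - pwilcox(U - 1, n1, n2))))
    method <- "exact"
  } else {
    p <- ranksum_p(z, tail)
    method <- "normal approximation"
  }
  structure(list(W = W, U_mw = U, z = z, p = p, n1 = n1, n2 = n2,
                 tail = tail, method = method),
            class = "ranksum_test")
}

ranksum_z <- function(W, mu, sigma, tail) {
  if (sigma == 0) return(0)
  if (tail == "right") (W - mu - 0.5) / sigma
  else (W - mu - 0.5 * sign(W - mu)) / sigma
}

ranksum_p <- function(z, tail) {
  if (tail == "right") 1 - pnorm(z) else 2 * (1 - pnorm(abs(z)))
}

#' @export
print.ranksum_test <- function(x, ...) {
  cat(sprintf("Rank-sum test (%s, %s tail): W = %g, U = %g, z = %.4f, p = %.4g (n1 = %d, n2 = %d)\n",
              x$method, x$tail, x$W, x$U_mw, x$z, x$p, x$n1, x$n2))
  invisible(x)
}

#' Recompute z and p from a reported rank-sum statistic
#'
#' Reproduces the normal-approximation z score and p-value from a published
#' rank sum `W` of group 1 and the two group sizes, without raw data (no tie
#' correction is possible).
#'
#' @param W Rank sum of group 1.
#' @param n1,n2 Group sizes.
#' @param tail `"right"` or `"two-sided"`.
#' @return List with `z` and `p`.
#' @export
ranksum_from_summary <- function(W, n1, n2, tail = c("right", "two-sided")) {
  tail <- match.arg(tail)
  W_min <- n1 * (n1 + 1) / 2
  W_max <- n1 * (n1 + 2 * n2 + 1) / 2
  if (W < W_min || W > W_max)
    stop("W = ", W, " is infeasible for group sizes ", n1, ", ", n2,
         " (range ", W_min, "-", W_max, ")")
  mu <- n1 * (n1 + n2 + 1) / 2
  sigma <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  z <- ranksum_z(W, mu, sigma, tail)
  list(z = z, p = ranksum_p(z, tail))
}

#' Holm (Bonferroni-Holm) step-down correction
#'
#' @param p_values Vector of p-values forming one test family.
#' @return Corrected p-values in the input order.
#' @export
holm <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "holm")
}

#' Bootstrap confidence interval for the unpaired median difference
#'
#' Effect size `median(x) - median(y)` with a 95% BCa interval from
#' `n_boot` stratified bootstrap resamples. Falls back to the percentile
#' interval (with a warning) when the BCa construction is degenerate, e.g.
#' for all-equal samples.
#'
#' @param x,y Numeric samples.
#' @param n_boot Bootstrap replicates (default 5000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `effect_size_ci`: list with `median_diff`,
#'   `ci_low`, `ci_high`, `n_boot`, `method`.
#' @export
bootstrap_median_diff <- function(x, y, n_boot = 5000, seed = 1L,
                                  conf = 0.95) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty")
  est <- median(x) - median(y)
  dat <- data.frame(v = c(x, y),
                    g = rep(1:2, c(length(x), length(y))))
  stat <- function(d, idx) {
    di <- d[idx, ]
    median(di$v[di$g == 1]) - median(di$v[di$g == 2])
  }
  set.seed(seed)
  b <- boot::boot(dat, stat, R = n_boot, strata = dat$g)
  ci <- tryCatch({
    out <- boot::boot.ci(b, conf = conf, type = "bca")
    c(out$bca[4], out$bca[5], method = "bca")
  }, error = function(e) NULL)
  if (is.null(ci)) {
    warning("BCa interval unavailable (degenerate resamples); ",
            "using the percentile interval")
    qs <- quantile(b$t[, 1], c((1 - conf) / 2, 1 - (1 - conf) / 2),
                   na.rm = TRUE, names = FALSE)
    ci <- c(qs, method = "percentile")
  }
  structure(list(median_diff = est,
                 ci_low = as.numeric(ci[1]), ci_high = as.numeric(ci[2]),
                 n_boot = n_boot, method = ci[["method"]]),
            class = "effect_size_ci")
}

#' @export
print.effect_size_ci <- function(x, ...) {
  cat(sprintf("median difference %.4g, 95%% CI [%.4g, %.4g] (%s, %d resamples)\n",
              x$median_diff, x$ci_low, x$ci_high, x$method, x$n_boot))
  invisible(x)
}

#' ROC curve, AUC and Youden-optimal sensitivity/specificity
#'
#' AUC is computed through the Mann-Whitney identity
#' `AUC = U / (n1 * n2)` with mid-ranks under ties. Sensitivity and
#' specificity are reported at the threshold maximising Youden's J
#' (`sens + spec - 1`); among ties the threshold with the higher
#' sensitivity is taken.
#'
#' @param scores Numeric classifier scores (higher = more likely positive).
#' @param labels Logical or 0/1 vector marking the positive class.
#' @return List with `auc`, `roc_curve` (data frame of threshold,
#'   sensitivity, specificity), `sensitivity`, `specificity`, `threshold`.
#' @export
roc_metrics <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("both classes must be present")
  pos <- scores[labels]; neg <- scores[!labels]
  n1 <- length(pos); n2 <- length(neg)
  W <- sum(rank(c(pos, neg))[seq_len(n1)])
  auc <- (W - n1 * (n1 + 1) / 2) / (n1 * n2)
  thr <- sort(unique(scores))
  curve <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(pos >= t), numeric(1)),
    specificity = vapply(thr, function(t) mean(neg < t), numeric(1)))
  j <- curve$sensitivity + curve$specificity - 1
  best <- which(j == max(j))
  best <- best[which.max(curve$sensitivity[best])]
  list(auc = auc, roc_curve = curve,
       sensitivity = curve$sensitivity[best],
       specificity = curve$specificity[best],
       threshold = curve$threshold[best])
}

#' Relative band power of one channel
#'
#' Welch power (2 s Hann windows, 50% overlap) integrated over `band`,
#' divided by the power in `total_band` (default 1-45 Hz). Intended for the
#' broadband re-referenced segment, before any band-pass.
#'
#' @param seg An [eeg_segment()].
#' @param band Numerator band in Hz (default `c(6, 9)`, low alpha).
#' @param channel Channel label or index.
#' @param total_band Denominator band in Hz (default `c(1, 45)`).
#' @param window_sec,overlap Welch window length (s) and overlap fraction.
#' @return Relative power in `[0, 1]`.
#' @export
relative_band_power <- function(seg, band = c(6, 9), channel,
                                total_band = c(1, 45), window_sec = 2,
                                overlap = 0.5) {
  stopifnot(inherits(seg, "eeg_segment"))
  if (band[2] > seg$fs / 2 || total_band[2] > seg$fs / 2)
    stop("band edges must be below the Nyquist frequency ", seg$fs / 2, " Hz")
  if (is.character(channel)) {
    idx <- match(channel, seg$channel_labels)
    if (is.na(idx)) stop("unknown channel: ", channel)
  } else idx <- channel
  psd <- welch_psd(seg$data[idx, ], seg$fs, window_sec, overlap)
  band_power(psd, band) / band_power(psd, total_band)
}

# Welch periodogram: Hann windows, mean over 50%-overlapping segments.
welch_psd <- function(x, fs, window_sec = 2, overlap = 0.5) {
  nw <- round(window_sec * fs)
  if (nw > length(x)) nw <- length(x)
  step <- max(1L, round(nw * (1 - overlap)))
  starts <- seq(1L, length(x) - nw + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nw) / (nw + 1)))
  scale <- fs * sum(w^2)
  spec <- rowMeans(vapply(starts, function(s) {
    seg <- (x[s:(s + nw - 1L)] - mean(x[s:(s + nw - 1L)])) * w
    (Mod(fft(seg))^2 / scale)[seq_len(floor(nw / 2) + 1L)]
  }, numeric(floor(nw / 2) + 1L)))
  # one-sided density
  if (nw %% 2 == 0) spec[2:(length(spec) - 1)] <- 2 * spec[2:(length(spec) - 1)]
  else spec[-1] <- 2 * spec[-1]
  list(freq = (seq_along(spec) - 1L) * fs / nw, psd = spec)
}

band_power <- function(psd, band) {
  in_band <- psd$freq >= band[1] & psd$freq <= band[2]
  if (!any(in_band)) stop("no frequency bins inside the requested band")
  sum(psd$psd[in_band])
}

#' Connectivity strength of one node
#'
#' Sum of in-strength and out-strength; for the symmetric PLV matrix this is
#' twice the row sum of significant weights.
#'
#' @param net A `functional_network`.
#' @param channel Channel label or index.
#' @return Strength (scalar, >= 0).
#' @export
node_strength <- function(net, channel) {
  stopifnot(inherits(net, "functional_network"))
  if (is.character(channel)) {
    idx <- match(channel, net$channel_labels)
    if (is.na(idx)) stop("unknown channel: ", channel)
  } else idx <- channel
  2 * sum(net$weights[idx, ])
}
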