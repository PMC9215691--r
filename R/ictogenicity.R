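#' Brain network ictogenicity at one coupling level
#'
#' BNI is the mean over nodes of the fraction of simulation time spent in
#' the seizure-like (rotating) state, averaged over `n_reps` independent
#' simulations.
#'
#' @param net A `functional_network` or weight matrix.
#' @param K Global coupling scale.
#' @param params A [theta_params()]; its `K` and `seed` are overridden.
#' @param n_reps Number of independent repetitions (default 2).
#' @param seed Root seed; per-repetition seeds derive from it.
#' @return BNI value in `[0, 1]`.
#' @export
bni <- function(net, K, params, n_reps = 2, seed = 1L) {
  stopifnot(n_reps >= 1)
  vals <- vapply(seq_len(n_reps), function(r) {
    p <- params
    p$K <- K
    p$seed <- derive_seed(seed, round(1000 * K), r)
    mean(simulate_theta(net, p)$seizure_fraction)
  }, numeric(1))
  mean(vals)
}

#' BNI curve over a coupling grid
#'
#' @inheritParams bni
#' @param K_grid Increasing vector of coupling values.
#' @return An object of class `bni_curve`: list with `K_grid`, `bni_values`,
#'   `n_reps`.
#' @export
bni_curve <- function(net, K_grid, params, n_reps = 2, seed = 1L) {
  if (is.unsorted(K_grid, strictly = TRUE))
    stop("K_grid must be strictly increasing")
  vals <- vapply(K_grid, function(K) bni(net, K, params, n_reps, seed),
                 numeric(1))
  structure(list(K_grid = K_grid, bni_values = vals, n_reps = n_reps),
            class = "bni_curve")
}

#' Coupling-robust BNI: area under BNI(K)
#'
#' Trapezoidal approximation of the integral of BNI(K) over `[K1, K2]` on a
#' uniform grid shared by all networks. The raw (unnormalised) area is
#' returned, so the range is `[0, K2 - K1]` (0 to 39 at the defaults).
#'
#' @inheritParams bni
#' @param K1,K2 Integration interval (defaults 1 and 40).
#' @param n_grid Number of grid points (default 40).
#' @param bni_fun Optional replacement for [bni()] with signature
#'   `(net, K, params, n_reps, seed)`; used to stub the simulator in tests
#'   and convergence checks.
#' @return The estimated area (scalar).
#' @export
bni_hat <- function(net, K1 = 1, K2 = 40, n_grid = 40, params,
                    n_reps = 2, seed = 1L, bni_fun = bni) {
  if (n_grid < 2) stop("n_grid must be at least 2")
  grid <- seq(K1, K2, length.out = n_grid)
  vals <- vapply(grid, function(K) bni_fun(net, K, params, n_reps, seed),
                 numeric(1))
  sum(diff(grid) * (head(vals, -1) + vals[-1]) / 2)
}

#' Calibrate the coupling scale to a target BNI
#'
#' Finds `K_star` with `bni(net, K_star) = target` (within `tol`), by a
#' coarse grid scan followed by bisection on the repetition-averaged BNI.
#'
#' @inheritParams bni_hat
#' @param target Calibration level (default 0.5).
#' @param tol Acceptable deviation from the target (default 0.05).
#' @param n_scan Coarse grid size for the initial bracketing scan.
#' @param max_iter Bisection iteration cap.
#' @return `K_star` (scalar).
#' @export
calibrate_K <- function(net, target = 0.5, tol = 0.05, K1 = 1, K2 = 40,
                        params, n_reps = 4, seed = 1L, n_scan = 9,
                        max_iter = 30, bni_fun = bni) {
  f <- function(K) bni_fun(net, K, params, n_reps, seed)
  scan_K <- seq(K1, K2, length.out = n_scan)
  # BNI(K) is non-decreasing on average, so scan upward and stop at the
  # first point at or above the target
  scan_v <- rep(NA_real_, n_scan)
  i <- NA_integer_
  for (k in seq_len(n_scan)) {
    scan_v[k] <- f(scan_K[k])
    if (scan_v[k] >= target) { i <- k; break }
  }
  if (is.na(i)) {
    if (abs(scan_v[which.min(abs(scan_v - target))] - target) <= tol)
      return(scan_K[which.min(abs(scan_v - target))])
    stop("network cannot reach BNI ", target, " within [", K1, ", ", K2, "]")
  }
  if (i == 1L) {
    if (abs(scan_v[1] - target) <= tol) return(scan_K[1])
    stop("network cannot reach BNI ", target, " within [", K1, ", ", K2, "]")
  }
  lo <- scan_K[i - 1]; hi <- scan_K[i]
  v_lo <- scan_v[i - 1]; v_hi <- scan_v[i]
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    v <- f(mid)
    if (abs(v - target) <= tol) return(mid)
    if (v < target) { lo <- mid; v_lo <- v } else { hi <- mid; v_hi <- v }
    if (hi - lo < 1e-3) break
  }
  (lo + hi) / 2
}

#' Node ictogenicity by single-node deletion
#'
#' For each node i the node (row and column) is removed, the network is
#' re-simulated at the calibrated coupling `K_star`, and
#' `NI(i) = (BNIpre - BNIpost(i)) / BNIpre` with `BNIpre` fixed at the
#' calibration level. `NI = 0` means removal had no effect; `NI = 1` means
#' removal abolished all seizure-like activity. The `K/N` normalisation uses
#' the reduced network size.
#'
#' @inheritParams bni
#' @param K_star Calibrated coupling (from [calibrate_K()]).
#' @param bni_pre Calibration level (default 0.5).
#' @return Named numeric vector of NI values (one per channel).
#' @export
node_ictogenicity <- function(net, K_star, params, n_reps = 4, seed = 1L,
                              bni_pre = 0.5, nodes = NULL) {
  w <- if (inherits(net, "functional_network")) net$weights else as.matrix(net)
  labels <- rownames(w)
  if (is.null(labels)) labels <- sprintf("node%d", seq_len(nrow(w)))
  if (nrow(w) < 2L) stop("network must have at least 2 nodes")
  if (is.null(nodes)) nodes <- seq_len(nrow(w))
  if (is.character(nodes)) nodes <- match(nodes, labels)
  ni <- vapply(nodes, function(i) {
    post <- bni(w[-i, -i, drop = FALSE], K_star, params, n_reps,
                seed = derive_seed(seed, 31L, i))
    (bni_pre - post) / bni_pre
  }, numeric(1))
  names(ni) <- labels[nodes]
  ni
}

#' Ictogenicity profile of one subject's segment networks
#'
#' Runs the full interrogation for each functional network: K-integrated
#' BNI, calibration of K to `bni_pre`, and per-node NI; then averages the
#' segment-level values into the subject profile used for group statistics.
#'
#' @param networks List of `functional_network`s (one per segment).
#' @param params A [theta_params()] at the desired scale.
#' @param K1,K2,n_grid BNI-hat integration settings.
#' @param n_reps_bni Repetitions per BNI-hat grid point (default 2).
#' @param n_reps_ni Repetitions for calibration and NI (default 4).
#' @param bni_pre Calibration level (default 0.5).
#' @param tol Calibration tolerance (default 0.05).
#' @param seed Root seed.
#' @param nodes Optional subset of nodes (indices or labels) for NI.
#' @return An object of class `ictogenicity_profile`: list with `bni_hat`
#'   (mean over segments), `ni` (named mean NI per node), `K_star` (per
#'   segment), per-segment values, and provenance.
#' @export
ictogenicity_profile <- function(networks, params, K1 = 1, K2 = 40,
                                 n_grid = 40, n_reps_bni = 2, n_reps_ni = 4,
                                 bni_pre = 0.5, tol = 0.05, seed = 1L,
                                 nodes = NULL) {
  stopifnot(length(networks) >= 1L)
  per_seg <- lapply(seq_along(networks), function(k) {
    net <- networks[[k]]
    sk <- derive_seed(seed, 41L, k)
    bh <- bni_hat(net, K1, K2, n_grid, params, n_reps_bni, seed = sk)
    ks <- calibrate_K(net, target = bni_pre, tol = tol, K1 = K1, K2 = K2,
                      params = params, n_reps = n_reps_ni,
                      seed = derive_seed(sk, 2L))
    ni <- node_ictogenicity(net, ks, params, n_reps_ni,
                            seed = derive_seed(sk, 3L),
                            bni_pre = bni_pre, nodes = nodes)
    list(bni_hat = bh, K_star = ks, ni = ni)
  })
  ni_mat <- do.call(rbind, lapply(per_seg, `[[`, "ni"))
  structure(list(
    bni_hat = mean(vapply(per_seg, `[[`, numeric(1), "bni_hat")),
    ni = colMeans(ni_mat),
    K_star = vapply(per_seg, `[[`, numeric(1), "K_star"),
    segments = per_seg,
    subject_id = networks[[1]]$provenance$subject),
    class = "ictogenicity_profile")
}
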