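#' Analysis configuration
#'
#' Collects every tunable of the pipeline with defaults matching the
#' canonical analysis: 250 Hz, 6-9 Hz fourth-order zero-phase band-pass,
#' 99 IAAFT surrogates with 10 iterations, theta model with `I0 = -1.2` and
#' `sigma = 0.6`, BNI integrated over `K` in `[1, 40]`, calibration to
#' `BNIpre = 0.5`, and 5000 bootstrap resamples. The `"fast"` profile
#' shrinks the simulation sizes (not the scientific constants) for smoke
#' runs and continuous testing.
#'
#' @param target_fs Sampling rate after downsampling (Hz).
#' @param band Pass band (Hz).
#' @param filter_order Butterworth order.
#' @param n_surrogates,n_iterations Surrogate count and IAAFT iterations.
#' @param level Surrogate exceedance fraction required for significance.
#' @param I0,noise_sd,dt Theta-model constants.
#' @param n_steps Integration steps per simulation.
#' @param K1,K2,n_grid BNI-hat integration settings.
#' @param n_reps_bni,n_reps_ni Simulation repetitions for BNI-hat grid
#'   points and for calibration/NI.
#' @param bni_target,tol Calibration level and tolerance.
#' @param n_boot Bootstrap resamples for effect sizes.
#' @param seed Root seed for the whole analysis.
#' @param profile `"standard"` or `"fast"`.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(target_fs = 250, band = c(6, 9), filter_order = 4,
                            n_surrogates = 99, n_iterations = 10,
                            level = 0.95,
                            I0 = -1.2, noise_sd = 0.6, dt = 0.01,
                            n_steps = 4e6, K1 = 1, K2 = 40, n_grid = 40,
                            n_reps_bni = 2, n_reps_ni = 4,
                            bni_target = 0.5, tol = 0.05,
                            n_boot = 5000, seed = 1L,
                            profile = c("standard", "fast")) {
  profile <- match.arg(profile)
  if (profile == "fast") {
    if (missing(n_steps)) n_steps <- 2e4
    if (missing(n_grid)) n_grid <- 8
    if (missing(n_reps_bni)) n_reps_bni <- 1
    if (missing(n_reps_ni)) n_reps_ni <- 2
    if (missing(n_surrogates)) n_surrogates <- 19
    if (missing(n_boot)) n_boot <- 500
  }
  structure(list(target_fs = target_fs, band = band,
                 filter_order = filter_order, n_surrogates = n_surrogates,
                 n_iterations = n_iterations, level = level, I0 = I0,
                 noise_sd = noise_sd, dt = dt, n_steps = n_steps, K1 = K1,
                 K2 = K2, n_grid = n_grid, n_reps_bni = n_reps_bni,
                 n_reps_ni = n_reps_ni, bni_target = bni_target, tol = tol,
                 n_boot = n_boot, seed = as.integer(seed), profile = profile),
            class = "analysis_config")
}

config_theta_params <- function(config, seed = config$seed) {
  theta_params(I0 = config$I0, noise_sd = config$noise_sd, dt = config$dt,
               n_steps = config$n_steps, seed = seed)
}

#' Run the full per-subject analysis
#'
#' Preprocesses each segment, builds its functional network, and computes
#' the subject's ictogenicity profile (BNI-hat, calibrated K, per-node NI,
#' averaged over segments).
#'
#' @param segments List of raw [eeg_segment()]s (1-3 per subject).
#' @param config An [analysis_config()].
#' @param nodes Optional subset of nodes (labels) for NI.
#' @param subject_seed Seed for this subject; defaults to the config seed.
#' @return An `ictogenicity_profile`, with the per-segment networks attached
#'   as attribute `"networks"` and the preprocessed segments as
#'   `"preprocessed"`.
#' @export
run_subject <- function(segments, config = analysis_config(), nodes = NULL,
                        subject_seed = config$seed) {
  stopifnot(length(segments) >= 1L)
  pre <- lapply(segments, preprocess_segment, target_fs = config$target_fs,
                band = config$band, order = config$filter_order)
  nets <- lapply(seq_along(pre), function(k)
    build_network(pre[[k]], n_surrogates = config$n_surrogates,
                  n_iterations = config$n_iterations,
                  seed = derive_seed(subject_seed, 7L, k),
                  band = config$band, order = config$filter_order,
                  level = config$level))
  prof <- ictogenicity_profile(
    nets, config_theta_params(config), K1 = config$K1, K2 = config$K2,
    n_grid = config$n_grid, n_reps_bni = config$n_reps_bni,
    n_reps_ni = config$n_reps_ni, bni_pre = config$bni_target,
    tol = config$tol, seed = derive_seed(subject_seed, 8L), nodes = nodes)
  attr(prof, "networks") <- nets
  attr(prof, "preprocessed") <- pre
  prof
}

#' Run the cohort-level analysis
#'
#' Computes every subject's ictogenicity profile and then the group-level
#' statistical layer: the one-sided BNI comparison, the one-sided occipital
#' NI tests (O1, O2; Holm-corrected as one family), the exploratory
#' two-sided scan over the remaining nodes (Holm-corrected as a second
#' family), bootstrap median-difference effect sizes, ROC metrics for the
#' best-separating occipital node, and the supplementary relative-power and
#' connectivity-strength comparisons.
#'
#' Subjects whose segments fail network construction or calibration are
#' excluded with a message; at least two subjects per group must survive.
#'
#' @param cohort An `eeg_cohort` (from [generate_cohort()] or
#'   [read_fixture()]), or a manifest directory path.
#' @param config An [analysis_config()].
#' @param output_dir Optional directory; when given, the per-subject profile
#'   CSV, the node-comparison CSV and a summary CSV are written there.
#' @param nodes Optional subset of nodes for NI (default: all channels).
#' @param progress Print one line per subject (default `FALSE`).
#' @return An object of class `cohort_report`: list with `profiles` (data
#'   frame), `bni_test`, `occipital_tests`, `node_table`, `roc`,
#'   `supplementary`, `excluded`.
#' @export
run_cohort <- function(cohort, config = analysis_config(), output_dir = NULL,
                       nodes = NULL, progress = FALSE) {
  if (is.character(cohort)) cohort <- read_fixture(cohort)
  stopifnot(inherits(cohort, "eeg_cohort"))
  subjects <- cohort$subjects
  profiles <- list()
  supp <- list()
  excluded <- character()
  for (s in seq_along(subjects)) {
    subj <- subjects[[s]]
    res <- tryCatch(
      run_subject(subj$segments, config, nodes = nodes,
                  subject_seed = derive_seed(config$seed, 101L, s)),
      error = function(e) e)
    if (inherits(res, "error")) {
      message("excluding subject ", subj$subject_id, ": ",
              conditionMessage(res))
      excluded <- c(excluded, subj$subject_id)
      next
    }
    if (progress)
      message(sprintf("subject %s (%s): bni_hat = %.2f",
                      subj$subject_id, subj$group, res$bni_hat))
    profiles[[length(profiles) + 1L]] <- c(
      list(subject_id = subj$subject_id, group = subj$group,
           bni_hat = res$bni_hat),
      as.list(res$ni))
    supp[[length(supp) + 1L]] <- supplementary_measures(
      subj, attr(res, "networks"), config)
  }
  prof_df <- do.call(rbind, lapply(profiles, function(p)
    as.data.frame(p, check.names = FALSE)))
  supp_df <- do.call(rbind, supp)
  if (is.null(prof_df) || length(unique(prof_df$group)) < 2L ||
      min(table(prof_df$group)) < 2L)
    stop("need at least two analysable subjects per group")
  report <- group_statistics(prof_df, supp_df, config)
  report$excluded <- excluded
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

# Occipital relative power (low alpha and alpha bands) and connectivity
# strength per subject, averaged over segments.
supplementary_measures <- function(subj, networks, config) {
  segs <- subj$segments
  vals <- lapply(c("O1", "O2"), function(ch) {
    if (!ch %in% segs[[1]]$channel_labels) return(NULL)
    rp_low <- mean(vapply(segs, function(sg)
      relative_band_power(rereference_average(downsample(sg, config$target_fs)),
                          band = c(6, 9), channel = ch), numeric(1)))
    rp_alpha <- mean(vapply(segs, function(sg)
      relative_band_power(rereference_average(downsample(sg, config$target_fs)),
                          band = c(7.5, 12.5), channel = ch), numeric(1)))
    strength <- mean(vapply(networks, node_strength, numeric(1), channel = ch))
    setNames(c(rp_low, rp_alpha, strength),
             paste0(c("rp_low_", "rp_alpha_", "strength_"), ch))
  })
  as.data.frame(as.list(unlist(vals)))
}

# The full statistical layer on the per-subject profile table.
group_statistics <- function(prof_df, supp_df, config) {
  is_ppr <- prof_df$group == "PPR"
  node_cols <- setdiff(names(prof_df), c("subject_id", "group", "bni_hat"))
  seed <- config$seed

  bni_rs <- ranksum(prof_df$bni_hat[is_ppr], prof_df$bni_hat[!is_ppr],
                    tail = "right", exact = FALSE)
  bni_es <- bootstrap_median_diff(prof_df$bni_hat[is_ppr],
                                  prof_df$bni_hat[!is_ppr],
                                  n_boot = config$n_boot,
                                  seed = derive_seed(seed, 201L))
  bni_test <- list(test = bni_rs, effect = bni_es)

  occ <- intersect(c("O1", "O2"), node_cols)
  occ_tests <- NULL
  if (length(occ)) {
    rows <- lapply(occ, function(ch)
      node_comparison(prof_df, ch, is_ppr, "right", config,
                      derive_seed(seed, 202L, match(ch, occ))))
    occ_tests <- do.call(rbind, rows)
    occ_tests$p_corrected <- holm(occ_tests$p)
  }

  others <- setdiff(node_cols, occ)
  node_table <- NULL
  if (length(others)) {
    rows <- lapply(others, function(ch)
      node_comparison(prof_df, ch, is_ppr, "two-sided", config,
                      derive_seed(seed, 203L, match(ch, others))))
    node_table <- do.call(rbind, rows)
    node_table$p_corrected <- holm(node_table$p)
  }

  roc <- NULL
  if ("O2" %in% node_cols)
    roc <- roc_metrics(prof_df[["O2"]], is_ppr)

  supplementary <- NULL
  if (!is.null(supp_df) && nrow(supp_df) == nrow(prof_df)) {
    rows <- lapply(names(supp_df), function(cn) {
      rs <- ranksum(supp_df[[cn]][is_ppr], supp_df[[cn]][!is_ppr],
                    tail = "right", exact = FALSE)
      es <- bootstrap_median_diff(supp_df[[cn]][is_ppr],
                                  supp_df[[cn]][!is_ppr],
                                  n_boot = config$n_boot,
                                  seed = derive_seed(seed, 204L, nchar(cn)))
      data.frame(measure = cn, p = rs$p, U = rs$W, z = rs$z,
                 effect_size = es$median_diff, ci_low = es$ci_low,
                 ci_high = es$ci_high)
    })
    supplementary <- do.call(rbind, rows)
  }

  structure(list(profiles = prof_df, bni_test = bni_test,
                 occipital_tests = occ_tests, node_table = node_table,
                 roc = roc, supplementary = supplementary),
            class = "cohort_report")
}

node_comparison <- function(prof_df, ch, is_ppr, tail, config, seed) {
  x <- prof_df[[ch]][is_ppr]; y <- prof_df[[ch]][!is_ppr]
  rs <- ranksum(x, y, tail = tail, exact = FALSE)
  es <- bootstrap_median_diff(x, y, n_boot = config$n_boot, seed = seed)
  data.frame(node = ch, p = rs$p, U = rs$W, z = rs$z,
             effect_size = es$median_diff, ci_low = es$ci_low,
             ci_high = es$ci_high)
}

write_report <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$profiles, file.path(output_dir, "subject_profiles.csv"),
            row.names = FALSE)
  if (!is.null(report$node_table))
    write.csv(report$node_table[, c("node", "p", "p_corrected", "U", "z",
                                    "effect_size", "ci_low", "ci_high")],
              file.path(output_dir, "node_comparison.csv"), row.names = FALSE)
  if (!is.null(report$occipital_tests))
    write.csv(report$occipital_tests,
              file.path(output_dir, "occipital_tests.csv"), row.names = FALSE)
  if (!is.null(report$supplementary))
    write.csv(report$supplementary,
              file.path(output_dir, "supplementary.csv"), row.names = FALSE)
  summary_df <- data.frame(
    measure = c("bni_p", "bni_z", "bni_W",
                if (!is.null(report$roc))
                  c("auc_O2", "sensitivity_O2", "specificity_O2")),
    value = c(report$bni_test$test$p, report$bni_test$test$z,
              report$bni_test$test$W,
              if (!is.null(report$roc))
                c(report$roc$auc, report$roc$sensitivity,
                  report$roc$specificity)))
  write.csv(summary_df, file.path(output_dir, "summary.csv"),
            row.names = FALSE)
  invisible(output_dir)
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n")
  cat(sprintf("  subjects: %d (%d PPR, %d nonPPR)%s\n",
              nrow(x$profiles), sum(x$profiles$group == "PPR"),
              sum(x$profiles$group == "nonPPR"),
              if (length(x$excluded))
                paste0("; excluded: ", paste(x$excluded, collapse = ", "))
              else ""))
  t <- x$bni_test$test
  cat(sprintf("  BNI (one-sided): W = %g, z = %.2f, p = %.3g\n",
              t$W, t$z, t$p))
  if (!is.null(x$occipital_tests)) {
    for (i in seq_len(nrow(x$occipital_tests)))
      cat(sprintf("  NI %s (one-sided): z = %.2f, corrected p = %.3g\n",
                  x$occipital_tests$node[i], x$occipital_tests$z[i],
                  x$occipital_tests$p_corrected[i]))
  }
  if (!is.null(x$roc))
    cat(sprintf("  ROC (NI of O2): AUC = %.2f, sens = %.2f, spec = %.2f\n",
                x$roc$auc, x$roc$sensitivity, x$roc$specificity))
  invisible(x)
}
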