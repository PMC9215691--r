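#' Write a cohort to disk as headered CSV files plus a manifest
#'
#' One CSV per segment (columns = channels, rows = samples) and a
#' `manifest.csv` with columns `subject_id`, `group`, `segment_file`, `fs`.
#'
#' @param cohort An `eeg_cohort` (or any list of subjects in the same shape).
#' @param directory Output directory; created if absent.
#' @return The manifest path, invisibly.
#' @export
write_fixture <- function(cohort, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (subj in cohort$subjects) {
    for (k in seq_along(subj$segments)) {
      seg <- subj$segments[[k]]
      fname <- sprintf("%s_seg%d.csv", subj$subject_id, k)
      df <- as.data.frame(t(seg$data))
      names(df) <- seg$channel_labels
      write.csv(df, file.path(directory, fname), row.names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subj$subject_id, group = subj$group,
        segment_file = fname, fs = seg$fs, stringsAsFactors = FALSE)
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(), group = character(),
               segment_file = character(), fs = numeric())
  path <- file.path(directory, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort written by [write_fixture()]
#'
#' @param directory Directory containing `manifest.csv` and the segment CSVs.
#' @return An `eeg_cohort` (without ground-truth coupling matrices).
#' @export
read_fixture <- function(directory) {
  path <- file.path(directory, "manifest.csv")
  if (!file.exists(path))
    stop("manifest not found: ", path)
  manifest <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                       error = function(e)
                         stop("could not parse manifest ", path, ": ",
                              conditionMessage(e)))
  need <- c("subject_id", "group", "segment_file", "fs")
  if (!all(need %in% names(manifest)))
    stop("manifest ", path, " lacks required columns: ",
         paste(setdiff(need, names(manifest)), collapse = ", "))
  subjects <- list()
  for (id in unique(manifest$subject_id)) {
    rows <- manifest[manifest$subject_id == id, , drop = FALSE]
    segs <- vector("list", nrow(rows))
    for (k in seq_len(nrow(rows))) {
      f <- file.path(directory, rows$segment_file[k])
      if (!file.exists(f))
        stop("manifest references a missing segment file: ",
             rows$segment_file[k])
      df <- read.csv(f, check.names = FALSE)
      segs[[k]] <- eeg_segment(t(as.matrix(df)), fs = rows$fs[k],
                               channel_labels = names(df),
                               subject_id = id,
                               segment_id = sprintf("seg%d", k))
    }
    subjects[[length(subjects) + 1L]] <-
      list(subject_id = id, group = rows$group[1], segments = segs)
  }
  structure(list(subjects = subjects, spec = NULL), class = "eeg_cohort")
}

#' Serialize a functional network
#'
#' Writes the weight matrix as a TSV with channel-label header plus a JSON
#' sidecar holding the phase lags and provenance.
#'
#' @param net A `functional_network`.
#' @param path_prefix Output path without extension; writes
#'   `<prefix>.tsv` and `<prefix>.json`.
#' @return `path_prefix`, invisibly.
#' @export
write_network <- function(net, path_prefix) {
  w <- as.data.frame(net$weights)
  names(w) <- net$channel_labels
  utils::write.table(w, paste0(path_prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  side <- list(channel_labels = net$channel_labels,
               lags = net$lags, provenance = net$provenance)
  jsonlite::write_json(side, paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path_prefix)
}

#' Read a functional network written by [write_network()]
#'
#' @param path_prefix Path prefix used at write time.
#' @return A `functional_network`.
#' @export
read_network <- function(path_prefix) {
  w <- as.matrix(utils::read.table(paste0(path_prefix, ".tsv"), sep = "\t",
                                   header = TRUE, check.names = FALSE))
  side <- jsonlite::read_json(paste0(path_prefix, ".json"),
                              simplifyVector = TRUE)
  functional_network(unname(w), matrix(unlist(side$lags), nrow(w), ncol(w)),
                     side$channel_labels, provenance = side$provenance)
}
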