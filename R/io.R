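# Dataset/feature containers and result tables.  Recordings, feature sets and
# forests are stored as self-describing named lists in RDS files (one file per
# subject-session); experiment tables are plain CSV.

#' Write a dataset to a directory
#'
#' One RDS container per recording, holding the named arrays `emg`
#' (`samples x C`), `label`, `repetition` and the scalar attributes `fs`,
#' `subject_id`, `session_id`.
#'
#' @param dataset List of `emg_recording` objects (e.g. from
#'   [synthesize_dataset()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in dataset) {
    payload <- list(container = "emgadapt_recording", version = 1L,
                    emg = rec$emg, label = rec$label,
                    repetition = rec$repetition, fs = rec$fs,
                    subject_id = rec$subject_id, session_id = rec$session_id)
    saveRDS(payload, file.path(dir, sprintf("s%s_sess%s.rds",
                                            rec$subject_id, rec$session_id)))
  }
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Directory of recording containers.
#' @return A list of `emg_recording` objects (class `emg_dataset`).
#' @export
read_dataset <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.rds$", full.names = TRUE))
  if (length(files) == 0) stop("no recording containers in ", dir)
  out <- list()
  for (f in files) {
    p <- readRDS(f)
    if (!identical(p$container, "emgadapt_recording")) {
      stop("not a recording container: ", f)
    }
    rec <- new_recording(p$emg, p$label, p$repetition, p$subject_id,
                         p$session_id, p$fs)
    out[[sprintf("s%s_sess%s", rec$subject_id, rec$session_id)]] <- rec
  }
  structure(out, class = "emg_dataset")
}

#' Write a windowed feature set to a file
#'
#' Named arrays `X`, `y`, `repetition` plus the attributes `feature_names`,
#' `fs` and identifiers, in the same container family as recordings.
#'
#' @param features An `emg_features` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "emg_features"))
  payload <- c(list(container = "emgadapt_features", version = 1L),
               unclass(features))
  saveRDS(payload, path)
  invisible(path)
}

#' Read a feature container written by [write_features()]
#'
#' @param path File path.
#' @return The `emg_features` object.
#' @export
read_features <- function(path) {
  p <- readRDS(path)
  if (!identical(p$container, "emgadapt_features")) {
    stop("not a feature container: ", path)
  }
  p$container <- NULL
  p$version <- NULL
  structure(p, class = "emg_features")
}

#' Read a NinaPro-style recording container
#'
#' Expects a container (RDS) with the named variables `emg` (`samples x C`),
#' `restimulus` (per-sample movement code) and `rerepetition` (per-sample
#' repetition index); the original MATLAB matrix files use exactly these
#' variable names and must be converted to RDS first.  Movement codes are
#' mapped to consecutive labels `1..G` (0 stays rest) and `rerepetition`
#' becomes the repetition stream.  A channel subset may be selected (e.g. the
#' first eight ring electrodes of a 14-channel montage), preserving column
#' order.
#'
#' @param path Container file path.
#' @param channels Optional integer vector of channel columns to keep.
#' @param fs Sampling rate attached to the recording if the container has no
#'   `fs` field (the Delsys acquisitions are 2 kHz class).
#' @return An `emg_recording`.
#' @export
read_ninapro <- function(path, channels = NULL, fs = 2000) {
  p <- readRDS(path)
  for (nm in c("emg", "restimulus", "rerepetition")) {
    if (is.null(p[[nm]])) stop("missing variable '", nm, "' in ", path)
  }
  emg <- as.matrix(p$emg)
  stim <- as.integer(p$restimulus)
  rept <- as.integer(p$rerepetition)
  if (length(stim) != nrow(emg) || length(rept) != nrow(emg)) {
    stop("shape mismatch: emg has ", nrow(emg), " samples, restimulus ",
         length(stim), ", rerepetition ", length(rept))
  }
  if (!is.null(channels)) {
    if (any(channels < 1 | channels > ncol(emg))) {
      stop("channel subset outside 1..", ncol(emg))
    }
    emg <- emg[, channels, drop = FALSE]
  }
  codes <- sort(unique(stim[stim != 0]))
  label <- integer(length(stim))
  label[stim != 0] <- match(stim[stim != 0], codes)
  new_recording(emg, label, rept,
                subject_id = p$subject_id %||% NA,
                session_id = p$session_id %||% NA,
                fs = p$fs %||% fs)
}

#' Write an experiment table to CSV
#'
#' Comma-separated with header `method,n_target_reps,seed,target_id,`
#' `balanced_accuracy`, accuracies with 6 decimals, rows ordered
#' deterministically by method (protocol order), repetitions, then seed.
#'
#' @param table An `emg_experiment_table` (or compatible data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  tab <- as.data.frame(table)
  need <- c("method", "n_target_reps", "seed", "target_id",
            "balanced_accuracy")
  if (!all(need %in% names(tab))) {
    stop("table must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(tab) > 0) {
    mlev <- union(experiment_methods(), unique(tab$method))
    ord <- order(match(tab$method, mlev), tab$n_target_reps, tab$seed,
                 tab$target_id)
    tab <- tab[ord, , drop = FALSE]
  }
  lines <- c(paste(need, collapse = ","),
             if (nrow(tab) > 0) {
               sprintf("%s,%d,%d,%s,%.6f", tab$method,
                       as.integer(tab$n_target_reps), as.integer(tab$seed),
                       as.character(tab$target_id), tab$balanced_accuracy)
             })
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read an experiment table written by [write_results()]
#'
#' @param path CSV file path.
#' @return An `emg_experiment_table` data frame.
#' @export
read_results <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(tab) <- c("emg_experiment_table", "data.frame")
  tab
}
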