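#' @keywords internal
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  # canonical text rendering -> md5; stable across sessions for plain lists
  writeLines(utils::capture.output(utils::str(x, digits.d = 12)), f)
  unname(tools::md5sum(f))
}

header_comment <- function(seed, hash) {
  sprintf("# tapsync run: seed=%s config_md5=%s", as.character(seed), hash)
}

write_tsv <- function(df, path, seed = NA, hash = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_comment(seed, hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

#' Write a long tap-event table
#'
#' One row per kept tap: `participant_id`, `group`, `condition`, `trial`,
#' `tap_time_s` (9 decimals, so a written table reads back to well within
#' 1 ns). A header comment records the seed and a config hash.
#'
#' @param dataset A `study_dataset`, or a data frame already in long
#'   format.
#' @param path Output path (TSV).
#' @return The path, invisibly.
#' @export
write_events_table <- function(dataset, path) {
  df <- if (is.data.frame(dataset)) dataset else events_table(dataset)
  seed <- if (inherits(dataset, "study_dataset")) dataset$design$seed else NA
  hash <- config_hash(if (inherits(dataset, "study_dataset")) dataset$design else df)
  df$tap_time_s <- sprintf("%.9f", df$tap_time_s)
  write_tsv(df, path, seed, hash)
  invisible(path)
}

#' Long event table of a study dataset
#'
#' @param dataset A `study_dataset`.
#' @return Data frame: `participant_id`, `group`, `condition`, `trial`,
#'   `tap_time_s`, `dropout_end_s` (NA when the trial had no dropout).
#' @export
events_table <- function(dataset) {
  stopifnot(inherits(dataset, "study_dataset"))
  grp <- stats::setNames(dataset$participants$group,
                         dataset$participants$participant_id)
  rows <- lapply(dataset$trials, function(trial) {
    t <- trial$events$times
    if (length(t) == 0L) return(NULL)
    data.frame(participant_id = trial$participant_id,
               group = grp[[trial$participant_id]],
               condition = trial$condition_name,
               trial = trial$trial,
               tap_time_s = t,
               dropout_end_s = if (is.null(trial$dropout_end)) NA_real_
                               else trial$dropout_end)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a long tap-event table
#'
#' Inverse of [write_events_table()]. Validates the header and returns
#' the long data frame; use [events_to_trials()] to regroup rows into
#' scorable trial objects.
#'
#' @param path TSV path.
#' @return Data frame with the [events_table()] columns.
#' @export
read_events_table <- function(path) {
  df <- read_tsv(path)
  needed <- c("participant_id", "condition", "trial", "tap_time_s")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop(sprintf("events table %s: missing column(s) %s",
                 path, paste(missing, collapse = ", ")))
  bad <- which(!is.finite(df$tap_time_s))
  if (length(bad))
    stop(sprintf("events table %s: non-numeric tap time at data row %d",
                 path, bad[1]))
  df
}

#' Regroup an event table into trial objects
#'
#' Rebuilds one `tap_trial` per (participant, condition, trial) triple,
#' attaching the condition's stimulus streams so the trials can be
#' scored.
#'
#' @param df Long event table (see [read_events_table()]).
#' @param duration Trial duration in seconds used to rebuild the
#'   stimulus trains.
#' @return List of `tap_trial` objects annotated like
#'   [generate_study()] output.
#' @export
events_to_trials <- function(df, duration = 39.5) {
  conditions <- lapply(CONDITIONS, condition_spec, duration = duration)
  names(conditions) <- CONDITIONS
  key <- interaction(df$participant_id, df$condition, df$trial, drop = TRUE)
  lapply(split(df, key), function(chunk) {
    cond <- conditions[[chunk$condition[1]]]
    trial <- structure(
      list(events = tap_events(sort(chunk$tap_time_s), source = "imported"),
           condition = cond,
           reference_stimuli = cond$reference_stimuli,
           secondary_stimuli = cond$secondary_stimuli,
           params = NULL),
      class = "tap_trial")
    trial$participant_id <- chunk$participant_id[1]
    trial$condition_name <- chunk$condition[1]
    trial$trial <- chunk$trial[1]
    trial$dropout_end <- if (!is.null(chunk$dropout_end_s) &&
                             is.finite(chunk$dropout_end_s[1]))
      chunk$dropout_end_s[1] else NULL
    trial
  })
}

#' Write / read a trial score table
#'
#' @param scores Score table from [score_study()].
#' @param path TSV path.
#' @param seed Seed recorded in the header comment.
#' @return The path (write) or the score table (read).
#' @export
write_scores_table <- function(scores, path, seed = NA) {
  write_tsv(scores, path, seed, config_hash(scores))
  invisible(path)
}

#' @rdname write_scores_table
#' @export
read_scores_table <- function(path) {
  read_tsv(path)
}

#' Write a stimulus-onset table
#'
#' Onsets of every stream of every condition, long format.
#'
#' @param conditions List of [condition_spec()] objects (defaults to the
#'   four study conditions).
#' @param path TSV path.
#' @return The path, invisibly.
#' @export
write_stimulus_table <- function(conditions = lapply(CONDITIONS, condition_spec),
                                 path) {
  rows <- lapply(conditions, function(cond) {
    streams <- list(cond$reference_stimuli)
    if (!is.null(cond$secondary_stimuli))
      streams <- c(streams, list(cond$secondary_stimuli))
    do.call(rbind, lapply(streams, function(s)
      data.frame(condition = cond$name, modality = s$modality,
                 rate_hz = s$rate, onset_s = sprintf("%.9f", s$onsets))))
  })
  write_tsv(do.call(rbind, rows), path)
  invisible(path)
}
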