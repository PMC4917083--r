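trial_columns <- c("subject_id", "session", "trial", "correct_sequences")
factor_columns <- c("subject_id", "piano", "age_group", "age_years",
                    "intelligence", "gender", "piano_hours", "delay")

schema_stop <- function(file, msg, rows = NULL) {
  where <- if (length(rows))
    sprintf(" (row%s %s)", if (length(rows) > 1) "s" else "",
            paste(utils::head(rows, 10), collapse = ", ")) else ""
  stop_arg("schema error in %s: %s%s", file, msg, where)
}

#' Read and validate a trial table
#'
#' Expects the CSV layout `subject_id,session,trial,correct_sequences` with
#' sessions `day1`/`day2`, 1-based integer trial indices, non-negative
#' performance values, and no duplicate (subject, session, trial) rows.
#'
#' @param path CSV path.
#' @return validated trial data frame.
#' @export
read_trials <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(trial_columns, names(tab))
  if (length(missing))
    schema_stop(path, paste("missing column(s):",
                            paste(missing, collapse = ", ")))
  bad <- which(!tab$session %in% c("day1", "day2"))
  if (length(bad)) schema_stop(path, "session must be 'day1' or 'day2'", bad)
  if (!is.numeric(tab$trial) || any(tab$trial < 1 | tab$trial != round(tab$trial)))
    schema_stop(path, "trial must be a positive integer",
                which(tab$trial < 1 | tab$trial != round(tab$trial)))
  if (!is.numeric(tab$correct_sequences) || anyNA(tab$correct_sequences) ||
      any(tab$correct_sequences < 0))
    schema_stop(path, "correct_sequences must be numeric and >= 0",
                which(is.na(tab$correct_sequences) | tab$correct_sequences < 0))
  key <- paste(tab$subject_id, tab$session, tab$trial)
  if (anyDuplicated(key))
    schema_stop(path, "duplicate (subject, session, trial)",
                which(duplicated(key)))
  tab[trial_columns]
}

#' Read and validate a subject-factor table
#'
#' Expects the CSV layout
#' `subject_id,piano,age_group,age_years,intelligence,gender,piano_hours,delay`
#' with the canonical binary levels and the 24h/30min delay labels.
#'
#' @param path CSV path.
#' @return validated subject data frame.
#' @export
read_factors <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(factor_columns, names(tab))
  if (length(missing))
    schema_stop(path, paste("missing column(s):",
                            paste(missing, collapse = ", ")))
  if (anyDuplicated(tab$subject_id))
    schema_stop(path, "duplicate subject_id",
                which(duplicated(tab$subject_id)))
  levels_of <- list(piano = c("non-player", "player"),
                    age_group = c("younger", "older"),
                    intelligence = c("control", "high"),
                    gender = c("female", "male"),
                    delay = c("24h", "30min"))
  for (nm in names(levels_of)) {
    bad <- which(!tab[[nm]] %in% levels_of[[nm]])
    if (length(bad))
      schema_stop(path, sprintf("unknown %s level (expected %s)", nm,
                                paste(levels_of[[nm]], collapse = "/")), bad)
  }
  if (!is.numeric(tab$age_years) || any(tab$age_years < 18 | tab$age_years > 70))
    schema_stop(path, "age_years must be numeric in [18, 70]",
                which(tab$age_years < 18 | tab$age_years > 70))
  if (!is.numeric(tab$piano_hours) || any(tab$piano_hours < 0))
    schema_stop(path, "piano_hours must be numeric and >= 0",
                which(tab$piano_hours < 0))
  tab[factor_columns]
}

check_referential <- function(trials, subjects) {
  orphans <- setdiff(unique(trials$subject_id), subjects$subject_id)
  if (length(orphans))
    stop_arg("trials reference subject(s) absent from the factor table: %s",
             paste(orphans, collapse = ", "))
  invisible(TRUE)
}

#' Write a simulated cohort to disk
#'
#' Writes `trials.csv` and `factors.csv` in the canonical layouts plus a
#' `ground_truth.yaml` sidecar holding every parameter the generator used.
#'
#' @param cohort a [scenario_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$factors[factor_columns],
                   file.path(dir, "factors.csv"), row.names = FALSE)
  truth <- cohort$truth
  truth$hypers <- as.list(as.data.frame(truth$hypers))
  truth$subject_params <- as.list(truth$subject_params)
  truth$gain_table <- as.list(truth$gain_table)
  truth$config$gain <- unclass(truth$config$gain)
  yaml::write_yaml(truth, file.path(dir, "ground_truth.yaml"),
                   precision = 15L)
  invisible(dir)
}
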