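# Plain-text round-tripping of the pipeline's tabular formats. Numeric text
# is written at full precision (15 significant digits survive a write/read
# round trip of doubles in practice; format uses digits = 17 where needed).

#' Write a regional timeseries to TSV
#'
#' Volumes in rows, regions in columns, header row of region IDs. Values are
#' written at full double precision so a write/read round trip is exact.
#'
#' @param ts A [regional_ts()].
#' @param path Output file path.
#' @export
write_timeseries_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "regional_ts"))
  df <- as.data.frame(ts$values)
  df[] <- lapply(df, function(col) format(col, digits = 17, trim = TRUE,
                                          scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a regional timeseries from TSV
#'
#' @param path TSV file, header row = region IDs.
#' @param tr_seconds,subject_id,session_id Metadata for the returned object.
#' @return A [regional_ts()].
#' @export
read_timeseries_tsv <- function(path, tr_seconds = 3,
                                subject_id = NA_character_,
                                session_id = NA_character_) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  if (!all(vapply(df, is.numeric, logical(1)))) {
    bad <- names(df)[!vapply(df, is.numeric, logical(1))]
    stop(sprintf("non-numeric timeseries column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  regional_ts(as.matrix(df), tr_seconds = tr_seconds,
              subject_id = subject_id, session_id = session_id)
}

subject_table_schema <- function() {
  c("subject_id", "age", "sex", "site", "cortical_thickness", "gm_volume",
    "tiv", "brain_age", "max_displacement")
}

#' Write / read the subject table (CSV)
#'
#' @param subjects data.frame with the subject-level columns (identifiers,
#'   demographics, brain-change measures, motion summary).
#' @param path CSV path.
#' @export
write_subject_table <- function(subjects, path) {
  utils::write.csv(subjects, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_subject_table
#' @export
read_subject_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(subject_table_schema(), names(df))
  if (length(missing_cols)) {
    stop(sprintf("subject table missing column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  num_cols <- setdiff(subject_table_schema(), "subject_id")
  bad <- num_cols[!vapply(df[num_cols], is.numeric, logical(1))]
  if (length(bad)) {
    stop(sprintf("non-numeric subject column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  df
}

#' Write a per-subject redundancy profile to JSON
#'
#' Emits the window labels, the per-window one-/two-connected densities and
#' the BFR score.
#'
#' @param profile A `redundancy_profile`.
#' @param path JSON output path.
#' @export
write_profile_json <- function(profile, path) {
  stopifnot(inherits(profile, "redundancy_profile"))
  jsonlite::write_json(
    list(subject_id = profile$subject_id,
         labels = profile$labels,
         d_one = profile$d_one,
         d_two = profile$d_two,
         session = profile$session,
         bfr = profile$bfr,
         n_windows = profile$n_windows),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' Per-session timeseries as TSV (`<subject>_ses-<s>.tsv`), the subject
#' table as `subjects.csv`, the cognitive scores as `cognitive_scores.csv`
#' and the generator truth record as `truth.yaml`.
#'
#' @param cohort A [gen_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sessions in cohort$timeseries) {
    for (ts in sessions) {
      write_timeseries_tsv(ts, file.path(dir, sprintf(
        "%s_ses-%s.tsv", ts$subject_id, ts$session_id)))
    }
  }
  write_subject_table(cohort$subjects, file.path(dir, "subjects.csv"))
  utils::write.csv(
    data.frame(subject_id = cohort$subjects$subject_id,
               cohort$cognitive_scores, check.names = FALSE),
    file.path(dir, "cognitive_scores.csv"), row.names = FALSE, quote = FALSE)
  truth <- cohort$truth
  truth$state_sequences <- lapply(truth$state_sequences,
                                  function(s) lapply(s, as.list))
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' Read cohort inputs from a directory
#'
#' Reads the subject table, cognitive scores and all per-session timeseries
#' written by [write_cohort()].
#'
#' @param dir Directory produced by [write_cohort()].
#' @param tr_seconds Repetition time metadata for the timeseries.
#' @return List with `timeseries` (per-subject list of sessions),
#'   `subjects`, `cognitive_scores`.
#' @export
read_cohort <- function(dir, tr_seconds = 3) {
  subjects <- read_subject_table(file.path(dir, "subjects.csv"))
  cog <- utils::read.csv(file.path(dir, "cognitive_scores.csv"),
                         check.names = FALSE)
  cog_mat <- as.matrix(cog[setdiff(names(cog), "subject_id")])
  rownames(cog_mat) <- cog$subject_id
  timeseries <- lapply(subjects$subject_id, function(sid) {
    files <- sort(list.files(dir, pattern = sprintf("^%s_ses-.*\\.tsv$", sid),
                             full.names = TRUE))
    if (length(files) == 0L) {
      stop(sprintf("no timeseries files found for subject %s", sid))
    }
    lapply(seq_along(files), function(s) {
      read_timeseries_tsv(files[s], tr_seconds = tr_seconds,
                          subject_id = sid, session_id = as.character(s))
    })
  })
  names(timeseries) <- subjects$subject_id
  list(timeseries = timeseries, subjects = subjects,
       cognitive_scores = cog_mat)
}
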