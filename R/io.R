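#' Write a simulated study to disk
#'
#' Serializes a [simulate_study()] result as plain files: `cohort.csv`,
#' `trials.csv`, `summaries.csv`, and `truth.json` (the planted paths and
#' ROI effects). Column names match the tibbles' names.
#'
#' @param sim A list from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$cohort, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$summaries, file.path(dir, "summaries.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(paths = as.list(sim$truth$paths), rois = sim$truth$rois),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read trial records from CSV
#'
#' Counterpart of [write_study()]'s `trials.csv`; validates the scoring
#' schema on read.
#'
#' @param path CSV with at least `participant_id`, `condition`,
#'   `rt_relative_clause`, `question_correct`.
#' @return A tibble of trial records.
#' @export
read_trials <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "condition", "rt_relative_clause",
            "question_correct")
  missing_cols <- setdiff(need, names(tr))
  if (length(missing_cols)) {
    stop("trial file is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tr$question_correct <- as.logical(tr$question_correct)
  tibble::as_tibble(tr)
}
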