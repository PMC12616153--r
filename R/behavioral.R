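#' Score self-paced-reading trials into per-participant summaries
#'
#' Computes, for every participant, comprehension accuracy and mean
#' relative-clause reading time per condition and pooled, plus the two
#' structural disadvantage scores:
#' \deqn{rtSDS = \bar{RT}_{SR} - \bar{RT}_{OR}, \qquad
#'       accSDS = \bar{Acc}_{OR} - \bar{Acc}_{SR}}
#' so that more negative values indicate relatively worse performance on the
#' noncanonical (object-relative) condition. Reading time is the
#' relative-clause region only; the other sentence regions are carried in
#' the trial records but not analyzed.
#'
#' @param trials Data frame of trial records with columns `participant_id`,
#'   `condition` ("SR"/"OR"), `rt_relative_clause` (seconds, > 0) and
#'   logical/0-1 `question_correct`.
#' @return A tibble, one row per participant: `participant_id`, `acc_sr`,
#'   `acc_or`, `acc_overall`, `rt_sr`, `rt_or`, `rt_overall`, `acc_sds`,
#'   `rt_sds`, `n_trials`, and `excluded` (all `FALSE`; see
#'   [apply_outlier_exclusion()]).
#' @export
score_trials <- function(trials) {
  required <- c("participant_id", "condition", "rt_relative_clause",
                "question_correct")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols)) {
    stop("trials are missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!all(trials$condition %in% c("SR", "OR"))) {
    stop("condition must be 'SR' or 'OR'", call. = FALSE)
  }
  if (any(trials$rt_relative_clause <= 0)) {
    stop("relative-clause RTs must be positive", call. = FALSE)
  }
  ids <- unique(trials$participant_id)
  both <- tapply(trials$condition, trials$participant_id,
                 function(cc) all(c("SR", "OR") %in% cc))
  if (!all(both[ids])) {
    stop("participant(s) missing a condition: ",
         paste(ids[!both[ids]], collapse = ", "), call. = FALSE)
  }
  correct <- as.numeric(trials$question_correct)
  f_id <- factor(trials$participant_id, levels = ids)
  is_sr <- trials$condition == "SR"

  agg <- function(x, sel) {
    tapply(x[sel], f_id[sel], mean)[ids]
  }
  acc_sr <- agg(correct, is_sr)
  acc_or <- agg(correct, !is_sr)
  acc_overall <- tapply(correct, f_id, mean)[ids]
  rt_sr <- agg(trials$rt_relative_clause, is_sr)
  rt_or <- agg(trials$rt_relative_clause, !is_sr)
  rt_overall <- tapply(trials$rt_relative_clause, f_id, mean)[ids]

  tibble::tibble(
    participant_id = ids,
    acc_sr = unname(acc_sr),
    acc_or = unname(acc_or),
    acc_overall = unname(acc_overall),
    rt_sr = unname(rt_sr),
    rt_or = unname(rt_or),
    rt_overall = unname(rt_overall),
    acc_sds = unname(acc_or - acc_sr),
    rt_sds = unname(rt_sr - rt_or),
    n_trials = as.integer(table(f_id)[ids]),
    excluded = FALSE
  )
}

#' Score a single participant's trials
#'
#' @param trials Trial records for one participant (both conditions
#'   present).
#' @return A one-row tibble as in [score_trials()].
#' @examples
#' tr <- data.frame(
#'   participant_id = "p1",
#'   condition = c("SR", "SR", "OR", "OR"),
#'   rt_relative_clause = c(2, 3, 4, 6),
#'   question_correct = c(TRUE, FALSE, TRUE, TRUE))
#' score_participant(tr)  # rt_sds = -2.5, acc_sds = +0.5
#' @export
score_participant <- function(trials) {
  if (length(unique(trials$participant_id)) != 1L) {
    stop("score_participant expects trials from exactly one participant",
         call. = FALSE)
  }
  score_trials(trials)
}

#' Flag behavioral outliers
#'
#' Marks a participant as excluded when a measure lies more than `k`
#' standard deviations from the cohort mean in \emph{both} conditions for
#' the same measure family: both condition RTs, or both condition
#' accuracies. Means and SDs are computed once on the full sample (no
#' iterative re-exclusion), on the raw (not z-scored) summaries. A
#' condition with zero SD excludes nobody on that measure.
#'
#' @param summaries Output of [score_trials()] (>= 2 participants).
#' @param k SD multiplier, default 3.
#' @return `summaries` with the `excluded` column updated.
#' @export
apply_outlier_exclusion <- function(summaries, k = 3) {
  if (nrow(summaries) < 2L) {
    stop("outlier exclusion needs at least 2 participants", call. = FALSE)
  }
  if (k < 0) stop("k must be nonnegative", call. = FALSE)
  extreme <- function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) return(rep(FALSE, length(x)))
    abs(x - mean(x)) > k * s
  }
  rt_flag <- extreme(summaries$rt_sr) & extreme(summaries$rt_or)
  acc_flag <- extreme(summaries$acc_sr) & extreme(summaries$acc_or)
  summaries$excluded <- rt_flag | acc_flag
  summaries
}
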