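#' Generate ROI feature tables with planted mediation structure
#'
#' Produces a participants x ROIs table of one imaging modality. Every ROI
#' declines (or grows) linearly with age at `roi_age_slope` feature units
#' per year plus Gaussian noise. ROIs named in `config$planted_rois`
#' instead carry an exact standardized mediation structure: the feature is
#' built as `a * age_z + sqrt(1 - a^2) * e` (so the standardized age ->
#' feature path is `a`), and the designated outcome column is rewritten as
#' a unit-variance blend of its original standardized values and the
#' feature residuals `e`, weighted so the standardized partial coefficient
#' of the feature in Y ~ X + M is exactly `b` in population. The rewritten
#' outcome is returned on the original column's raw scale.
#'
#' @param cohort Cohort tibble (scored, so the outcome column exists).
#' @param truth A `synthetic_truth` object from [generate_cohort()]; the
#'   planted ROI paths are appended to it.
#' @param config A [synthetic_config()]; `n_rois`, `planted_rois`,
#'   `roi_baseline`, `roi_age_slope`, `roi_noise_sd` are used.
#' @param outcome Name of the cohort column that planted b-paths feed
#'   (default `"rt_sds"`).
#' @param modality Label stored on the table ("GMV" or "pALFF").
#' @return A list:
#'   \describe{
#'     \item{features}{`roi_feature_table`: tibble with `participant_id`
#'       and one column per ROI; attributes `modality` and `roi_info`
#'       (roi/hemisphere/group).}
#'     \item{cohort}{the cohort, with the outcome column rewritten when
#'       effects are planted.}
#'     \item{truth}{`truth` with the planted `a`, `b`, `ab` recorded.}
#'   }
#' @export
generate_roi_features <- function(cohort, truth, config,
                                  outcome = "rt_sds", modality = "GMV") {
  validate_synthetic_config(config)
  roi_info <- config_roi_set(config)
  planted <- config$planted_rois
  if (!is.null(planted)) {
    unknown <- setdiff(planted$roi, roi_info$roi)
    if (length(unknown)) {
      stop("planted ROI(s) not in the ROI set: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (!outcome %in% names(cohort)) {
      stop(sprintf("outcome column '%s' not present in the cohort", outcome),
           call. = FALSE)
    }
  }
  n <- nrow(cohort)
  with_seed(derive_seed(config$seed, paste0("roi_", modality)), {
    age_z <- standardize(cohort$age)
    feat <- matrix(NA_real_, nrow = n, ncol = nrow(roi_info),
                   dimnames = list(NULL, roi_info$roi))
    resid_store <- list()
    for (j in seq_len(nrow(roi_info))) {
      roi <- roi_info$roi[j]
      p_idx <- if (!is.null(planted)) match(roi, planted$roi) else NA
      if (!is.na(p_idx)) {
        a <- planted$a[p_idx]
        e <- stats::rnorm(n)
        m_z <- a * age_z + sqrt(1 - a^2) * e
        resid_store[[roi]] <- e
        # map the standardized feature onto the modality's raw scale,
        # keeping the configured age trend direction
        sd_feat <- sqrt((config$roi_age_slope * stats::sd(cohort$age))^2 +
                          config$roi_noise_sd^2)
        feat[, j] <- config$roi_baseline +
          config$roi_age_slope * mean(cohort$age) + sd_feat * m_z
      } else {
        feat[, j] <- config$roi_baseline +
          config$roi_age_slope * cohort$age +
          stats::rnorm(n, 0, config$roi_noise_sd)
      }
    }

    if (!is.null(planted) && nrow(planted) > 0) {
      y_raw <- cohort[[outcome]]
      y_z <- standardize(y_raw)
      load2 <- sum(planted$b^2 * (1 - planted$a^2))
      if (load2 >= 1) {
        stop("planted b-paths too large: combined loading must be < 1",
             call. = FALSE)
      }
      y_new <- sqrt(1 - load2) * y_z
      for (p_idx in seq_len(nrow(planted))) {
        roi <- planted$roi[p_idx]
        e <- resid_store[[roi]]
        y_new <- y_new +
          planted$b[p_idx] * sqrt(1 - planted$a[p_idx]^2) * e
      }
      cohort[[outcome]] <- mean(y_raw) + stats::sd(y_raw) * y_new
      truth$rois <- rbind(
        truth$rois,
        tibble::tibble(roi = planted$roi, a = planted$a, b = planted$b,
                       ab = planted$a * planted$b))
    }

    features <- tibble::as_tibble(as.data.frame(feat))
    features <- tibble::add_column(features,
                                   participant_id = cohort$participant_id,
                                   .before = 1)
    attr(features, "modality") <- modality
    attr(features, "roi_info") <- roi_info
    class(features) <- c("roi_feature_table", class(features))
    list(features = features, cohort = cohort, truth = truth)
  })
}

#' ROI metadata of a feature table
#'
#' @param features A `roi_feature_table`.
#' @return The `roi`/`hemisphere`/`group` tibble stored on the table.
#' @export
roi_info <- function(features) {
  info <- attr(features, "roi_info")
  if (is.null(info)) {
    rois <- setdiff(names(features), "participant_id")
    info <- tibble::tibble(
      roi = rois,
      hemisphere = ifelse(startsWith(rois, "R_"), "R", "L"),
      group = NA_character_)
  }
  info
}
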