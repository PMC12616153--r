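#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (capped at 1, monotone via the cumulative
#' minimum from the largest rank). Thin wrapper over
#' `p.adjust(method = "BH")`; in the ROI analyses adjustment is applied
#' separately within each hemisphere x modality family.
#'
#' @param pvals Numeric vector of p-values in [0, 1] (may be empty).
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Partial correlation of each ROI feature with age
#'
#' Residualizes both the ROI feature and age on the covariates (with
#' intercept) and correlates the residuals; p-values come from the t
#' distribution on `n - k - 2` degrees of freedom, where `k` is the number
#' of covariates. Indirectly reproduces the "where is this modality
#' correlated with age" map that precedes the mediation analyses.
#'
#' @param roi_table A `roi_feature_table` (participant_id + ROI columns).
#' @param cohort Cohort table carrying `age` and the covariates, aligned by
#'   `participant_id`.
#' @param covariates Character vector of cohort covariate columns.
#' @param tails "two" (default) or "one" (p for the observed sign).
#' @return Tibble: `roi`, `hemisphere`, `n_used`, `partial_r`, `t`, `p`,
#'   and `p_fdr` adjusted within hemisphere.
#' @export
age_correlation_map <- function(roi_table, cohort,
                                covariates = c("sex", "education"),
                                tails = c("two", "one")) {
  tails <- match.arg(tails)
  info <- roi_info(roi_table)
  merged <- merge(as.data.frame(roi_table),
                  as.data.frame(cohort)[, c("participant_id", "age",
                                            covariates)],
                  by = "participant_id")
  k <- length(covariates)
  rows <- lapply(info$roi, function(roi) {
    cols <- stats::complete.cases(merged[, c(roi, "age", covariates)])
    d <- merged[cols, ]
    n <- nrow(d)
    if (n < k + 3L) {
      stop("fewer rows than covariates + 3 for ROI ", roi, call. = FALSE)
    }
    Z <- cbind(1, as.matrix(d[, covariates, drop = FALSE]))
    r_roi <- stats::.lm.fit(Z, d[[roi]])$residuals
    r_age <- stats::.lm.fit(Z, d$age)$residuals
    r <- stats::cor(r_roi, r_age)
    df <- n - k - 2L
    tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
    p <- if (tails == "two") 2 * stats::pt(-abs(tval), df) else
      stats::pt(-abs(tval), df)
    tibble::tibble(roi = roi, n_used = n, partial_r = r, t = tval, p = p)
  })
  out <- do.call(rbind, rows)
  out <- merge(info[, c("roi", "hemisphere")], out, by = "roi", sort = FALSE)
  out <- tibble::as_tibble(out[match(info$roi, out$roi), ])
  out$p_fdr <- stats::ave(out$p, out$hemisphere,
                          FUN = function(p) bh_fdr(p))
  out
}

#' Configuration for a ROI mediation analysis
#'
#' Encodes one of the study's analysis designs: X = age, M = one ROI's
#' feature value, Y = a behavioral or memory outcome, with the modality's
#' covariate policy. Gray-matter models include total intracranial volume
#' as a nuisance covariate alongside sex and education; pALFF models do
#' not. Memory scores can be added as covariates singly or jointly, and the
#' memory-mediation design uses `outcome = "nih_wm"` (covariate
#' `"nih_stm"`) or vice versa.
#'
#' @param outcome Cohort column used as Y (e.g. `"rt_sds"`, `"acc_overall"`,
#'   `"nih_wm"`).
#' @param modality "GMV" or "pALFF"; sets the TIV covariate policy.
#' @param memory_covariates Any of `"nih_wm"`, `"nih_stm"` to control for
#'   memory capacity.
#' @param extra_covariates Additional covariate columns; default sex and
#'   education.
#' @param tiv_column Name of the TIV column (GMV models only).
#' @param alpha,n_boot,tails,expected_sign_ab,robust,seed Passed through to
#'   [mediation_spec()]; robust IRLS with one-tailed bias-corrected
#'   bootstrap p-values is the default, matching the imaging analyses.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(outcome,
                            modality = c("GMV", "pALFF"),
                            memory_covariates = character(),
                            extra_covariates = c("sex", "education"),
                            tiv_column = "tiv",
                            alpha = 0.05, n_boot = 5000,
                            tails = "one", expected_sign_ab = NULL,
                            robust = TRUE, seed = 1L) {
  modality <- match.arg(modality)
  covariates <- extra_covariates
  if (modality == "GMV") covariates <- c(covariates, tiv_column)
  covariates <- c(covariates, memory_covariates)
  structure(list(outcome = outcome, modality = modality,
                 covariates = covariates, alpha = alpha,
                 n_boot = as.integer(n_boot), tails = tails,
                 expected_sign_ab = expected_sign_ab, robust = robust,
                 seed = seed),
            class = "analysis_config")
}

#' ROI-wise mediation with per-hemisphere FDR
#'
#' Runs one [bootstrap_mediation()] per ROI with X = age, M = the ROI's
#' feature, Y = the configured outcome, and the modality's covariates.
#' Indirect-effect p-values are Benjamini-Hochberg adjusted separately
#' within each hemisphere (and the modality label is carried so families
#' are hemisphere x modality). Each ROI's bootstrap stream is seeded from
#' `(seed, ROI name)`, so adding or removing ROIs does not perturb the
#' others' resamples. `t_indirect` is the bootstrap mean divided by the
#' bootstrap SD of the indirect effect — a descriptive statistic used for
#' painting stat maps, not an inferential one.
#'
#' @param cohort Cohort table with `participant_id`, `age`, the outcome and
#'   covariates.
#' @param roi_table A `roi_feature_table` aligned by `participant_id`.
#' @param cfg An [analysis_config()].
#' @return A tibble, one row per ROI: identifiers, `n_used`, the five
#'   standardized paths, their p-values, `t_indirect`, `p_ab_fdr`, and
#'   logical `significant` at `cfg$alpha`.
#' @export
run_roi_mediation <- function(cohort, roi_table, cfg) {
  info <- roi_info(roi_table)
  rois <- info$roi
  if (length(rois) < 2L) stop("need at least 2 ROIs", call. = FALSE)
  missing_rois <- setdiff(rois, names(roi_table))
  if (length(missing_rois)) {
    stop("ROI(s) missing from the feature table: ",
         paste(missing_rois, collapse = ", "), call. = FALSE)
  }
  need <- c("participant_id", "age", cfg$outcome, cfg$covariates)
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  merged <- merge(as.data.frame(cohort)[, need],
                  as.data.frame(roi_table), by = "participant_id")

  rows <- lapply(seq_along(rois), function(i) {
    roi <- rois[i]
    spec <- mediation_spec(
      x_name = "age", m_name = roi, y_name = cfg$outcome,
      covariates = cfg$covariates, n_boot = cfg$n_boot,
      alpha = cfg$alpha, tails = cfg$tails,
      expected_sign_ab = cfg$expected_sign_ab, robust = cfg$robust,
      seed = derive_seed(cfg$seed, roi))
    res <- bootstrap_mediation(merged, spec)
    tibble::tibble(
      roi = roi, hemisphere = info$hemisphere[i],
      modality = cfg$modality, outcome = cfg$outcome,
      n_used = res$n_used,
      beta_a = res$beta_a, beta_b = res$beta_b, beta_c = res$beta_c,
      beta_c_prime = res$beta_c_prime, beta_ab = res$beta_ab,
      p_a = res$p_a, p_b = res$p_b, p_c = res$p_c,
      p_c_prime = res$p_c_prime, p_ab = res$p_ab,
      t_indirect = res$boot_mean_ab / res$boot_sd_ab,
      n_boot_effective = res$n_boot_effective)
  })
  out <- do.call(rbind, rows)
  out$p_ab_fdr <- stats::ave(out$p_ab, out$hemisphere,
                             FUN = function(p) bh_fdr(p))
  out$significant <- out$p_ab_fdr <= cfg$alpha
  out
}

#' The behavioral mediation suite
#'
#' The eight behavioral path models: mediator (working memory or
#' short-term memory) x outcome (overall accuracy, accuracy disadvantage
#' score, overall relative-clause RT, RT disadvantage score), each with sex
#' and education as nuisance covariates, one-tailed bias-corrected
#' bootstrap p-values, and the directional hypothesis that older age works
#' through reduced memory toward worse performance (indirect effect
#' negative for accuracy and the disadvantage scores, positive for overall
#' RT).
#'
#' @param cohort Scored cohort (exclusions applied) with columns `age`,
#'   `nih_wm`, `nih_stm`, `sex`, `education` and the four outcomes.
#' @param n_boot Bootstrap resamples per model (default 5000).
#' @param seed Master seed; each model derives a child stream.
#' @param robust Use bisquare IRLS for the path fits (default `FALSE`,
#'   matching an ordinary-least-squares behavioral analysis).
#' @return Tibble with one row per mediator x outcome: the five
#'   standardized paths and their p-values.
#' @export
behavioral_mediation_suite <- function(cohort, n_boot = 5000, seed = 1L,
                                       robust = FALSE) {
  if (any(cohort$excluded %||% FALSE)) {
    cohort <- cohort[!cohort$excluded, ]
  }
  mediators <- c(wm = "nih_wm", stm = "nih_stm")
  outcomes <- c("acc_overall", "acc_sds", "rt_overall", "rt_sds")
  rows <- list()
  for (m in names(mediators)) {
    for (y in outcomes) {
      expected <- if (y == "rt_overall") "+" else "-"
      spec <- mediation_spec(
        x_name = "age", m_name = mediators[[m]], y_name = y,
        covariates = c("sex", "education"), n_boot = n_boot,
        tails = "one", expected_sign_ab = expected, robust = robust,
        seed = derive_seed(seed, paste(m, y, sep = ":")))
      res <- bootstrap_mediation(cohort, spec)
      rows[[paste(m, y)]] <- tibble::tibble(
        mediator = mediators[[m]], outcome = y, n_used = res$n_used,
        beta_a = res$beta_a, beta_b = res$beta_b, beta_c = res$beta_c,
        beta_c_prime = res$beta_c_prime, beta_ab = res$beta_ab,
        p_a = res$p_a, p_b = res$p_b, p_c = res$p_c,
        p_c_prime = res$p_c_prime, p_ab = res$p_ab)
    }
  }
  do.call(rbind, unname(rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Paint a ROI statistic into a volume
#'
#' Writes one statistic per ROI into the atlas geometry (every voxel of a
#' ROI gets the ROI's value; background stays 0), producing a NIfTI-ready
#' stat map — the tabular substitute for brain-surface renders.
#'
#' @param atlas An [atlas_volume()] whose `label_map$roi` covers every ROI
#'   in `table`.
#' @param table Result tibble with a `roi` column (e.g. from
#'   [run_roi_mediation()]).
#' @param stat Name of the numeric column to paint.
#' @return A `volume3d`.
#' @export
write_stat_map <- function(atlas, table, stat) {
  if (!inherits(atlas, "atlas_volume")) {
    stop("atlas must be an atlas_volume", call. = FALSE)
  }
  if (!stat %in% names(table)) {
    stop(sprintf("unknown stat field '%s'", stat), call. = FALSE)
  }
  out <- array(0, dim = dim(atlas$data))
  if (nrow(table) == 0L) {
    return(volume3d(out, voxel_mm = atlas$voxel_mm))
  }
  idx <- match(table$roi, atlas$label_map$roi)
  if (anyNA(idx)) {
    stop("ROI(s) not present in the atlas: ",
         paste(table$roi[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(table))) {
    out[atlas$data == atlas$label_map$label[idx[i]]] <- table[[stat]][i]
  }
  volume3d(out, voxel_mm = atlas$voxel_mm)
}
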