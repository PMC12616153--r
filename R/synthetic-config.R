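#' Configuration for the synthetic study generator
#'
#' Collects every constant the synthetic cohort, trial, ROI-feature, and BOLD
#' phantom generators use. The defaults emulate the published study
#' conditions: a bimodal adult age distribution spanning 20-80 years, an
#' age -> working-memory standardized slope of -0.61 and age -> short-term
#' memory slope of -0.54, self-paced-reading response times and accuracies
#' calibrated to the cohort's descriptive statistics (object-relative
#' relative-clause RT 2.89 s (SD 1.28), accuracy 86.6% (8.4%);
#' subject-relative 2.43 s (0.99), 89.7% (8.8%)), 24 trials per condition,
#' 12 language ROIs per hemisphere, and a 427-volume resting-state phantom at
#' TR 1.65 s.
#'
#' RT generation works on the log scale: trial RTs are lognormal (positive,
#' right-skewed), with the condition mean/SD moment-matched to the targets
#' and a participant-level slowing term that grows with age, slightly
#' steeper for the object-relative condition so the RT structural
#' disadvantage score becomes more negative with age.
#'
#' @param n_participants Number of participants.
#' @param seed Master seed; every generator derives its own child stream from
#'   it via [derive_seed()].
#' @param age_mixture Data frame with columns `mean`, `sd`, `weight` (years);
#'   weights must sum to 1. Ages are clipped to `age_range`.
#' @param age_range Closed interval ages are clipped to, years.
#' @param path_age_wm,path_age_stm Standardized slopes of working memory and
#'   short-term memory on age.
#' @param memory_residual_cor Correlation of the WM and STM residuals (the
#'   two tasks tap overlapping memory systems).
#' @param sr_rt_mean,sr_rt_sd,or_rt_mean,or_rt_sd Target mean and SD (in
#'   seconds, across participants) of the per-participant mean
#'   relative-clause RT in each condition.
#' @param sr_acc,or_acc Target mean comprehension accuracy per condition.
#' @param trials_per_condition Trials per sentence structure per participant.
#' @param rt_trial_log_sd Within-participant trial-to-trial SD of log RT.
#' @param rt_age_slope_sr,rt_age_slope_or Participant-level age slowing on
#'   the log-RT scale, per SD of age; the object-relative slope is the larger
#'   one by default.
#' @param acc_wm_slope Logit-scale slope of trial accuracy on standardized
#'   working memory.
#' @param acc_subject_sd SD of the participant-level logit accuracy offset.
#' @param n_rois ROIs per hemisphere (the default language set has 12).
#' @param planted_rois `NULL`, or a data frame with columns `roi`, `a`, `b`:
#'   ROIs that carry a planted mediation effect with standardized a-path
#'   (age -> feature) `a` and b-path (feature -> outcome, given age) `b`.
#' @param roi_baseline Mean feature value at age 0, arbitrary units.
#' @param roi_age_slope Feature change per year of age (negative emulates
#'   gray-matter decline).
#' @param roi_noise_sd SD of the ROI feature noise, feature units.
#' @param tiv_mean_female,tiv_mean_male,tiv_sd Total intracranial volume
#'   parameters, mL (invented; the source study does not report them).
#' @param education_probs Probabilities of education levels 1-6 (invented to
#'   match a reported mean near 5.1 and SD near 1).
#' @param prop_female Proportion of female participants.
#' @param wm_score_mean,wm_score_sd,stm_score_mean,stm_score_sd Raw-score
#'   scale of the two memory tests.
#' @param phantom_shape Integer voxel grid dimensions of the BOLD phantom.
#' @param phantom_n_volumes Time points in the phantom (427 by default).
#' @param phantom_tr Repetition time, seconds (1.65 by default).
#' @param phantom_inband_freq,phantom_outband_freq Frequencies (Hz) of the
#'   in-band and out-of-band sinusoid blocks; must lie below the Nyquist
#'   frequency for `phantom_tr`.
#' @param phantom_noise_sd Additive Gaussian noise floor on every phantom
#'   voxel, signal units.
#' @return An object of class `synthetic_config` (a validated list).
#' @seealso [generate_cohort()], [generate_trials()],
#'   [generate_roi_features()], [generate_phantom_bold()]
#' @export
synthetic_config <- function(n_participants = 187,
                             seed = 1L,
                             age_mixture = data.frame(
                               mean = c(30, 67), sd = c(7, 8),
                               weight = c(0.45, 0.55)),
                             age_range = c(20, 80),
                             path_age_wm = -0.61,
                             path_age_stm = -0.54,
                             memory_residual_cor = 0.4,
                             sr_rt_mean = 2.43, sr_rt_sd = 0.99,
                             or_rt_mean = 2.89, or_rt_sd = 1.28,
                             sr_acc = 0.897, or_acc = 0.866,
                             trials_per_condition = 24,
                             rt_trial_log_sd = 0.35,
                             rt_age_slope_sr = 0.10,
                             rt_age_slope_or = 0.115,
                             acc_wm_slope = 0.25,
                             acc_subject_sd = 0.30,
                             n_rois = 12,
                             planted_rois = NULL,
                             roi_baseline = 0.7,
                             roi_age_slope = -0.002,
                             roi_noise_sd = 0.05,
                             tiv_mean_female = 1400,
                             tiv_mean_male = 1550,
                             tiv_sd = 110,
                             education_probs = c(0.01, 0.02, 0.05,
                                                 0.12, 0.38, 0.42),
                             prop_female = 0.74,
                             wm_score_mean = 107.96, wm_score_sd = 13.88,
                             stm_score_mean = 26.17, stm_score_sd = 6.39,
                             phantom_shape = c(12L, 6L, 6L),
                             phantom_n_volumes = 427L,
                             phantom_tr = 1.65,
                             phantom_inband_freq = 0.05,
                             phantom_outband_freq = 0.20,
                             phantom_noise_sd = 0.1) {
  cfg <- as.list(environment())
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!is.numeric(cfg$n_participants) || cfg$n_participants < 1) {
    stop("n_participants must be a positive count", call. = FALSE)
  }
  mx <- cfg$age_mixture
  if (!is.data.frame(mx) || !all(c("mean", "sd", "weight") %in% names(mx))) {
    stop("age_mixture needs columns mean, sd, weight", call. = FALSE)
  }
  if (abs(sum(mx$weight) - 1) > 1e-8) {
    stop("age_mixture weights must sum to 1", call. = FALSE)
  }
  if (any(mx$sd <= 0)) stop("age_mixture sds must be positive", call. = FALSE)
  for (p in c("sr_acc", "or_acc")) {
    if (cfg[[p]] <= 0 || cfg[[p]] > 1) {
      stop(sprintf("%s must lie in (0, 1]", p), call. = FALSE)
    }
  }
  for (p in c("sr_rt_sd", "or_rt_sd", "rt_trial_log_sd", "roi_noise_sd",
              "tiv_sd")) {
    if (cfg[[p]] <= 0) stop(sprintf("%s must be positive", p), call. = FALSE)
  }
  if (cfg$trials_per_condition < 1) {
    stop("trials_per_condition must be >= 1", call. = FALSE)
  }
  if (cfg$phantom_tr <= 0) stop("phantom_tr must be positive", call. = FALSE)
  if (length(cfg$phantom_shape) != 3L || any(cfg$phantom_shape < 3)) {
    stop("phantom_shape needs >= 3 voxels per axis", call. = FALSE)
  }
  nyq <- 1 / (2 * cfg$phantom_tr)
  if (cfg$phantom_inband_freq > nyq || cfg$phantom_outband_freq > nyq) {
    stop(sprintf("phantom sinusoid frequency above the Nyquist limit %.4f Hz",
                 nyq), call. = FALSE)
  }
  if (!is.null(cfg$planted_rois)) {
    pr <- cfg$planted_rois
    if (!is.data.frame(pr) || !all(c("roi", "a", "b") %in% names(pr))) {
      stop("planted_rois needs columns roi, a, b", call. = FALSE)
    }
    if (any(abs(pr$a) >= 1) || any(abs(pr$b) >= 1)) {
      stop("planted standardized paths must lie in (-1, 1)", call. = FALSE)
    }
  }
  invisible(cfg)
}

#' The default bilateral language ROI set
#'
#' Twelve regions per hemisphere in three functional groups of four:
#' frontal cortex (IFG pars triangularis, opercularis, orbitalis; middle
#' frontal gyrus), mid-to-anterior temporal lobe (MTG, STG and their
#' temporal poles), and the temporoparietal junction (posterior MTG/STG,
#' supramarginal and angular gyri). ROI names are prefixed `L_` / `R_`.
#'
#' @return A tibble with columns `roi`, `hemisphere` ("L"/"R"), `group`.
#' @export
default_roi_set <- function() {
  base <- c("IFGtri", "IFGoper", "IFGorb", "MFG",
            "MTG", "STG", "MTGpole", "STGpole",
            "pMTG", "pSTG", "SMG", "AG")
  group <- rep(c("frontal", "anterior_temporal", "temporoparietal"),
               each = 4L)
  tibble::tibble(
    roi = c(paste0("L_", base), paste0("R_", base)),
    hemisphere = rep(c("L", "R"), each = length(base)),
    group = rep(group, 2L)
  )
}

# ROI names for a configured number per hemisphere; falls back to generic
# names when n differs from the canonical 12
config_roi_set <- function(cfg) {
  if (cfg$n_rois == 12) return(default_roi_set())
  base <- sprintf("ROI%02d", seq_len(cfg$n_rois))
  tibble::tibble(
    roi = c(paste0("L_", base), paste0("R_", base)),
    hemisphere = rep(c("L", "R"), each = cfg$n_rois),
    group = NA_character_
  )
}
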