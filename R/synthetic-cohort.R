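#' Generate a synthetic cohort
#'
#' Draws participant-level variables: age from a two-component Gaussian
#' mixture clipped to the configured range (bimodal by default, mirroring a
#' lifespan cohort thin in middle age), working-memory and short-term-memory
#' scores as standardized linear functions of standardized age with the
#' configured slopes plus correlated Gaussian residuals scaled so the
#' marginal variance is 1, sex as Bernoulli, education on a 1-6 scale, and
#' total intracranial volume as Gaussian with a sex offset.
#'
#' @param config A [synthetic_config()] object.
#' @return A list with elements:
#'   \describe{
#'     \item{cohort}{tibble, one row per participant: `participant_id`,
#'       `age`, `sex` (1 = female, 0 = male), `education`, `tiv`,
#'       `nih_wm`, `nih_stm` plus the internal standardized scores
#'       `age_z`, `wm_z`, `stm_z`.}
#'     \item{truth}{a `synthetic_truth` list carrying the planted behavioral
#'       slopes and (initially empty) planted ROI paths.}
#'   }
#' @examples
#' cs <- generate_cohort(synthetic_config(n_participants = 50, seed = 1))
#' head(cs$cohort)
#' @export
generate_cohort <- function(config) {
  validate_synthetic_config(config)
  n <- as.integer(config$n_participants)
  with_seed(derive_seed(config$seed, "cohort"), {
    mx <- config$age_mixture
    comp <- sample.int(nrow(mx), n, replace = TRUE, prob = mx$weight)
    age <- stats::rnorm(n, mx$mean[comp], mx$sd[comp])
    age <- pmin(pmax(age, config$age_range[1]), config$age_range[2])
    age_z <- standardize(age)

    rho <- config$memory_residual_cor
    e1 <- stats::rnorm(n)
    e2 <- stats::rnorm(n)
    p_wm <- config$path_age_wm
    p_stm <- config$path_age_stm
    wm_z <- p_wm * age_z + sqrt(1 - p_wm^2) * e1
    stm_z <- p_stm * age_z +
      sqrt(1 - p_stm^2) * (rho * e1 + sqrt(1 - rho^2) * e2)

    sex <- stats::rbinom(n, 1L, config$prop_female)
    education <- sample(1:6, n, replace = TRUE, prob = config$education_probs)
    tiv_mean <- ifelse(sex == 1L, config$tiv_mean_female,
                       config$tiv_mean_male)
    tiv <- stats::rnorm(n, tiv_mean, config$tiv_sd)

    cohort <- tibble::tibble(
      participant_id = sprintf("P%04d", seq_len(n)),
      age = age,
      sex = sex,
      education = education,
      tiv = tiv,
      nih_wm = config$wm_score_mean + config$wm_score_sd * wm_z,
      nih_stm = config$stm_score_mean + config$stm_score_sd * stm_z,
      age_z = age_z,
      wm_z = wm_z,
      stm_z = stm_z
    )
    truth <- structure(
      list(paths = c(age_wm = p_wm, age_stm = p_stm),
           rois = tibble::tibble(roi = character(), a = numeric(),
                                 b = numeric(), ab = numeric())),
      class = "synthetic_truth")
    list(cohort = cohort, truth = truth)
  })
}

# Solve lognormal (meanlog, sdlog) from a target mean and sd by moment
# matching: sdlog^2 = log(1 + (sd/mean)^2), meanlog = log(mean) - sdlog^2/2.
lognormal_params <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# Between-participant log-scale variance needed so the SD across
# participants of the per-trial-averaged RT matches the target, after
# removing the share contributed by within-participant trial noise.
between_subject_logvar <- function(mean, sd, trial_log_sd, n_trials) {
  trial_share <- (exp(trial_log_sd^2) - 1) / n_trials
  v <- (sd / mean)^2 - trial_share
  if (v <= 0) {
    stop("rt_trial_log_sd too large for the target between-participant SD",
         call. = FALSE)
  }
  log(1 + v)
}

#' Generate trial-level self-paced-reading data
#'
#' Emits `trials_per_condition` subject-relative (SR) and object-relative
#' (OR) trials per participant (24 + 24 = 48 under defaults). Relative-clause
#' RTs are lognormal with condition-specific parameters moment-matched to the
#' configured mean/SD targets; a participant-level slowing term on the log
#' scale grows with age and is steeper for OR, so the RT structural
#' disadvantage score becomes more negative with age. Comprehension
#' correctness is Bernoulli at the condition accuracy, shifted on the logit
#' scale by the participant's working memory and an idiosyncratic offset.
#' Condition means are recentered against the drawn cohort so the expected
#' cohort mean equals the configured target exactly.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param config The same [synthetic_config()].
#' @return A tibble of trials: `participant_id`, `condition` ("SR"/"OR"),
#'   `trial`, the four region RTs in seconds (`rt_subject`,
#'   `rt_relative_clause`, `rt_main_clause`, `rt_modifier`),
#'   `question_type`, and logical `question_correct`.
#' @export
generate_trials <- function(cohort, config) {
  validate_synthetic_config(config)
  if (!is.data.frame(cohort) || nrow(cohort) == 0L) {
    stop("cohort must be a nonempty data frame", call. = FALSE)
  }
  n <- nrow(cohort)
  k <- as.integer(config$trials_per_condition)
  with_seed(derive_seed(config$seed, "trials"), {
    age_z <- cohort$age_z
    wm_z <- cohort$wm_z

    conds <- list(
      SR = list(mean = config$sr_rt_mean, sd = config$sr_rt_sd,
                slope = config$rt_age_slope_sr, acc = config$sr_acc),
      OR = list(mean = config$or_rt_mean, sd = config$or_rt_sd,
                slope = config$rt_age_slope_or, acc = config$or_acc)
    )
    v_between <- vapply(conds, function(cc) {
      between_subject_logvar(cc$mean, cc$sd, config$rt_trial_log_sd, k)
    }, numeric(1))
    # one participant effect shared across conditions plus a
    # condition-specific top-up so each condition hits its own variance
    slopes2 <- vapply(conds, function(cc) cc$slope^2, numeric(1))
    tau2 <- min(v_between - slopes2)
    if (tau2 < 0) {
      stop("rt age slopes too large for the target RT variances",
           call. = FALSE)
    }
    u <- stats::rnorm(n, 0, sqrt(tau2))
    subj_logit <- stats::rnorm(n, 0, config$acc_subject_sd)

    out <- vector("list", 2L)
    for (ci in seq_along(conds)) {
      cname <- names(conds)[ci]
      cc <- conds[[ci]]
      extra2 <- v_between[ci] - cc$slope^2 - tau2
      offset <- cc$slope * age_z + u +
        stats::rnorm(n, 0, sqrt(max(extra2, 0)))
      # recenter multiplicatively so the cohort-average expected RT equals
      # the configured condition mean for this drawn cohort
      offset <- offset - log(mean(exp(offset)))
      meanlog_i <- log(cc$mean) - config$rt_trial_log_sd^2 / 2 + offset

      # accuracy: logit offset chosen so the cohort mean equals the target
      lin <- config$acc_wm_slope * wm_z + subj_logit
      delta <- stats::uniroot(
        function(d) mean(stats::plogis(stats::qlogis(cc$acc) + d + lin)) -
          cc$acc,
        interval = c(-5, 5), tol = 1e-10)$root
      p_i <- stats::plogis(stats::qlogis(cc$acc) + delta + lin)

      idx <- rep(seq_len(n), each = k)
      rc_rt <- stats::rlnorm(n * k, meanlog_i[idx], config$rt_trial_log_sd)
      correct <- stats::rbinom(n * k, 1L, p_i[idx]) == 1L
      qtype <- rep_len(c("relative-clause-probe", "main-clause-probe"),
                       n * k)
      out[[ci]] <- tibble::tibble(
        participant_id = cohort$participant_id[idx],
        condition = cname,
        trial = rep(seq_len(k), n),
        rt_subject = stats::rlnorm(n * k, log(0.8), 0.3),
        rt_relative_clause = rc_rt,
        rt_main_clause = stats::rlnorm(n * k, log(1.0), 0.3),
        rt_modifier = stats::rlnorm(n * k, log(0.9), 0.3),
        question_type = qtype,
        question_correct = correct
      )
    }
    trials <- rbind(out[[1]], out[[2]])
    trials[order(match(trials$participant_id, cohort$participant_id)), ]
  })
}

#' Simulate a full synthetic study
#'
#' Convenience wrapper: cohort, trials, behavioral scoring and outlier
#' exclusion, in the order the analysis applies them.
#'
#' @param config A [synthetic_config()].
#' @return A list with `cohort` (participant covariates joined with the
#'   behavioral summaries), `trials`, `summaries`, and `truth`.
#' @export
simulate_study <- function(config) {
  cs <- generate_cohort(config)
  trials <- generate_trials(cs$cohort, config)
  summaries <- apply_outlier_exclusion(score_trials(trials))
  cohort <- merge(cs$cohort, summaries, by = "participant_id", sort = FALSE)
  cohort <- tibble::as_tibble(cohort[match(cs$cohort$participant_id,
                                           cohort$participant_id), ])
  list(cohort = cohort, trials = trials, summaries = summaries,
       truth = cs$truth)
}
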