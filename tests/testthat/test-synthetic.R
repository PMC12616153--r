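test_that("cohort generation recovers the configured age-memory slopes", {
  cfg <- synthetic_config(n_participants = 5000, seed = 101)
  cs <- generate_cohort(cfg)
  co <- cs$cohort
  sl_wm <- unname(coef(lm(scale(nih_wm) ~ scale(age), co))[2])
  sl_stm <- unname(coef(lm(scale(nih_stm) ~ scale(age), co))[2])
  # standard error of a standardized slope at this n is about 0.011
  expect_lt(abs(sl_wm - (-0.61)), 3.5 * sqrt((1 - 0.61^2) / 5000))
  expect_lt(abs(sl_stm - (-0.54)), 3.5 * sqrt((1 - 0.54^2) / 5000))
  expect_true(all(co$age >= 20 & co$age <= 80))
  expect_true(all(co$education %in% 1:6))

  cfg0 <- synthetic_config(n_participants = 5000, seed = 101,
                           path_age_wm = 0)
  sl0 <- unname(coef(lm(scale(nih_wm) ~ scale(age),
                        generate_cohort(cfg0)$cohort))[2])
  expect_lt(abs(sl0), 3.5 / sqrt(5000))
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- synthetic_config(n_participants = 40, seed = 7)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$trials, s2$trials)
  p1 <- generate_phantom_bold(cfg)
  p2 <- generate_phantom_bold(cfg)
  expect_identical(p1$bold$data, p2$bold$data)
})

test_that("trial structure and symmetric-condition nulls hold", {
  cfg <- synthetic_config(n_participants = 200, seed = 3)
  cs <- generate_cohort(cfg)
  trials <- generate_trials(cs$cohort, cfg)
  counts <- table(trials$participant_id, trials$condition)
  expect_true(all(counts == 24))
  expect_equal(nrow(trials), 200 * 48)

  # equal condition parameters and no age effects: SDS centered on zero
  cfg_sym <- synthetic_config(
    n_participants = 800, seed = 13,
    or_rt_mean = 2.4, or_rt_sd = 1.0, sr_rt_mean = 2.4, sr_rt_sd = 1.0,
    sr_acc = 0.88, or_acc = 0.88,
    rt_age_slope_sr = 0, rt_age_slope_or = 0)
  sim <- simulate_study(cfg_sym)
  se_rt <- sd(sim$summaries$rt_sds) / sqrt(nrow(sim$summaries))
  se_acc <- sd(sim$summaries$acc_sds) / sqrt(nrow(sim$summaries))
  expect_lt(abs(mean(sim$summaries$rt_sds)), 4 * se_rt)
  expect_lt(abs(mean(sim$summaries$acc_sds)), 4 * se_acc)
})

test_that("config validation rejects bad inputs", {
  expect_error(synthetic_config(n_participants = 0), "positive")
  expect_error(synthetic_config(age_mixture = data.frame(
    mean = c(30, 67), sd = c(7, 8), weight = c(0.5, 0.6))), "sum to 1")
  expect_error(synthetic_config(or_acc = 1.2), "in \\(0, 1\\]")
  expect_error(synthetic_config(trials_per_condition = 0), ">= 1")
  expect_error(synthetic_config(phantom_inband_freq = 0.4), "Nyquist")
  expect_error(synthetic_config(planted_rois = data.frame(
    roi = "L_pSTG", a = -1.2, b = 0.3)), "paths")
})

test_that("planted ROI effects are recoverable by direct OLS", {
  cfg <- synthetic_config(
    n_participants = 2000, seed = 31,
    planted_rois = data.frame(roi = "L_pSTG", a = -0.5, b = 0.4))
  sim <- simulate_study(cfg)
  rf <- generate_roi_features(sim$cohort, sim$truth, cfg,
                              outcome = "rt_sds")
  expect_equal(rf$truth$rois$ab, rf$truth$rois$a * rf$truth$rois$b)
  az <- as.numeric(scale(rf$cohort$age))
  mz <- as.numeric(scale(rf$features$L_pSTG))
  yz <- as.numeric(scale(rf$cohort$rt_sds))
  a_hat <- unname(coef(lm(mz ~ az))[2])
  b_hat <- unname(coef(lm(yz ~ az + mz))[3])
  # sampling error of each path at n = 2000 is about 0.02
  expect_lt(abs(a_hat - (-0.5)), 0.08)
  expect_lt(abs(b_hat - 0.4), 0.08)
  expect_lt(abs(a_hat * b_hat - (-0.2)), 0.05)

  # a negative age slope makes every non-planted ROI decline with age
  other <- setdiff(roi_info(rf$features)$roi, "L_pSTG")
  cors <- vapply(other, function(r) cor(rf$features[[r]], rf$cohort$age),
                 numeric(1))
  expect_true(all(cors < 0))
})

test_that("zero planted effects leave no ROI-outcome partial association", {
  cfg <- synthetic_config(n_participants = 1500, seed = 41)
  sim <- simulate_study(cfg)
  rf <- generate_roi_features(sim$cohort, sim$truth, cfg)
  az <- as.numeric(scale(rf$cohort$age))
  yz <- as.numeric(scale(rf$cohort$rt_sds))
  bs <- vapply(roi_info(rf$features)$roi, function(r) {
    mz <- as.numeric(scale(rf$features[[r]]))
    unname(coef(lm(yz ~ az + mz))[3])
  }, numeric(1))
  # each partial slope has SE ~ 1/sqrt(n); allow 4 SE across 24 ROIs
  expect_true(all(abs(bs) < 4 / sqrt(1500)))

  expect_error(
    generate_roi_features(sim$cohort, sim$truth,
                          synthetic_config(planted_rois = data.frame(
                            roi = "nope", a = 0.1, b = 0.1))),
    "not in the ROI set")
})

test_that("phantom blocks carry the designed spectral content", {
  # 400 volumes at TR 1.65 puts both sinusoids exactly on the FFT grid, so
  # "identical up to phase" means identical amplitude spectra
  cfg <- synthetic_config(seed = 9, phantom_n_volumes = 400L,
                          phantom_noise_sd = 0)
  ph <- generate_phantom_bold(cfg)
  expect_equal(dim(ph$bold$data)[4], 400L)
  lab <- ph$atlas$data
  vox <- which(lab == 1L)
  flat <- matrix(ph$bold$data, ncol = 400L)
  specs <- apply(flat[vox, ], 1, function(x) Mod(fft(x)))
  expect_lt(max(apply(specs, 1, function(r) diff(range(r)))), 1e-6)
})

test_that("a simulated study round-trips through CSV/JSON", {
  cfg <- synthetic_config(
    n_participants = 15, seed = 19,
    planted_rois = data.frame(roi = "L_SMG", a = -0.3, b = 0.2))
  sim <- simulate_study(cfg)
  rf <- generate_roi_features(sim$cohort, sim$truth, cfg)
  sim$truth <- rf$truth
  dir <- tempfile("study")
  write_study(sim, dir)
  expect_setequal(list.files(dir),
                  c("cohort.csv", "trials.csv", "summaries.csv",
                    "truth.json"))
  tr <- read_trials(file.path(dir, "trials.csv"))
  expect_equal(nrow(tr), nrow(sim$trials))
  expect_equal(score_trials(tr)$rt_sds, sim$summaries$rt_sds,
               tolerance = 1e-12)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$paths$age_wm, -0.61)
  expect_equal(truth$rois$ab, -0.06)
  unlink(dir, recursive = TRUE)
})
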