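---
title: "Region-based mediation of age-related sentence processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-based mediation of age-related sentence processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package addresses

Older adults largely retain language abilities but often slow down or err on
syntactically complex sentences, such as object-relative (OR) clauses
("the journalist who *the editor complimented* revised the article")
compared with subject-relative (SR) clauses ("the journalist who
*complimented the editor* ..."). Two broad explanations compete: age erodes
domain-general memory capacity, which complex sentences lean on; or age
erodes language-specific machinery, with memory playing a secondary role.
Mediation analysis can arbitrate: if the age effect on sentence processing
runs *through* working memory (WM) or short-term memory (STM), memory is a
mediator; if a direct age path remains after accounting for memory, something
else is at work. The same logic extends to the brain: regional gray-matter
volume (GMV) or resting-state activity (pALFF) in language cortex may carry
part of the age effect.

`roimediate` implements this analysis end to end — behavioral scoring,
ROI feature extraction, robust path models with bootstrap inference, and
per-hemisphere FDR — together with synthetic generators that plant known
effects, so every stage can be validated against ground truth without any
imaging data.

## The path model

For independent variable $X$ (age), mediator $M$, outcome $Y$, and nuisance
covariates $Z$, three regressions (each with intercept and the same $Z$)
define five standardized paths:

* $a$: slope of $X$ in $M \sim X + Z$
* $b$, $c'$: slopes of $M$ and $X$ in $Y \sim X + M + Z$
* $c$: slope of $X$ in $Y \sim X + Z$ (total effect)
* $ab = a \cdot b$ (indirect effect)

$X$, $M$, $Y$ are z-scored on the complete-case analysis sample, so the
paths are standardized coefficients, and in OLS mode the decomposition
$c = c' + ab$ holds to machine precision. Rows with any missing value among
the used columns are dropped listwise, which is why different
ROIs/modalities can have different model $n$s.

### Robust estimation

The imaging analyses fit each regression by iteratively reweighted least
squares with Tukey bisquare weights (tuning constant 4.685, residual scale
MAD/0.6745, iterated until the largest coefficient change falls below
`tol`). With well-behaved data the estimates track OLS; gross outliers are
smoothly downweighted to zero beyond the tuning radius. `irls_bisquare()`
is written in-package so it can sit inside the bootstrap's inner loop, and
the test suite cross-checks it against an independent robust fitter
(`MASS::rlm` with the same psi, tuning, and scale estimator). Note that
even on clean Gaussian data a bisquare fit is not numerically identical to
OLS — it is a different (95%-efficient) estimator — so exact agreement is
only expected as residual noise shrinks.

### Bias-corrected bootstrap inference

Inference on every path uses a nonparametric bootstrap with participants as
the resampling unit (`n_boot` = 5000 by default). The whole estimator —
including the z-scoring of $X$, $M$, $Y$ — is recomputed inside each
resample; a flag (`fixed_scaling`) switches to reusing the full-sample
scales. Resamples in which a fit degenerates (for instance a constant
column after resampling) are redrawn so the effective number of resamples
stays fixed; more than 10% redraws aborts with a diagnostic.

For a path estimate $\hat\theta$ with bootstrap draws $\theta^*$, the
median-bias constant is
$\hat z_0 = \Phi^{-1}\!\big(\#\{\theta^* < \hat\theta\}/B\big)$
(proportions clipped to $[1/(B+1),\,B/(B+1)]$). The bias-corrected (BC,
not accelerated) bound at level $\alpha$ reads the bootstrap quantile at
$\Phi(2\hat z_0 + z_\alpha)$, and the p-value is defined by confidence
interval inversion: the smallest $\alpha$ at which the one-sided BC bound
excludes zero, located by binary search to $10^{-4}$. The one-tailed
direction for $ab$ is declared a priori (`expected_sign_ab`), mirroring a
directional hypothesis — an estimate opposite in sign yields $p \ge 0.5$.
Two-tailed p-values double the smaller one-sided value, capped at 1. The
acceleration constant of BCa is deliberately omitted: only bias correction
is applied, and the choice is exposed in the documentation rather than
buried. A Sobel test (`sobel_test()`) is included purely as an independent
asymptotic check; at large $n$ its two-tailed p-value and the BC bootstrap
p agree closely, which the tests verify.

### Analysis designs and FDR families

`run_roi_mediation()` fits one model per ROI with $X$ = age, $M$ = the
ROI's feature, and $Y$ = a behavioral or memory outcome. Covariate policy
follows the modality: GMV models include total intracranial volume (TIV)
alongside sex and education; pALFF models omit TIV. Memory scores can be
added singly or jointly, and setting $Y$ = WM with STM as covariate (or
vice versa) yields the memory-mediation design. Indirect-effect p-values
are Benjamini–Hochberg adjusted *separately per hemisphere within each
modality* — left and right hemispheres are scientifically distinct
families here, and pooling them provably changes adjusted values. The
reported `t_indirect` (bootstrap mean / bootstrap SD of $ab$) is a
descriptive statistic for painting stat maps, not an inferential quantity.

Each ROI's bootstrap stream is seeded by hashing (master seed, ROI name),
so adding or removing ROIs never perturbs the other ROIs' resamples, and a
full pipeline run is bit-reproducible under a master seed.

## Behavioral scoring

Scoring collapses trials to per-participant summaries. "RT" is the reading
time on the relative-clause region only — the region where SR and OR
diverge — averaged per condition; accuracy comes from the comprehension
questions. The structural disadvantage scores are defined as
rtSDS = SR RT − OR RT and accSDS = OR acc − SR acc, so more negative values
mean relatively worse OR performance. Outlier exclusion flags a participant
only when a measure is more than $k$ SD (default 3) from the cohort mean in
*both* conditions of the same measure family (both RTs, or both
accuracies); means and SDs are computed once on the full sample, on raw
summaries, with no iterative re-exclusion. Mixed extremity (RT in one
condition, accuracy in another) does not exclude. Z-transformation happens
after exclusion, at modeling time, and the SDS is computed on raw means
first and z-scored afterwards — differencing first preserves the printed
SDS definitions.

## ROI features

**GMV.** Segmented gray-matter maps are smoothed with an isotropic Gaussian
kernel (8 mm FWHM default; per-axis sigma in voxels is
$\mathrm{FWHM}/(\mathrm{voxel\ size}\cdot 2\sqrt{2\ln 2})$), then averaged
over atlas labels. The kernel is truncated at 6 sigma and renormalized at
volume boundaries, so constants are preserved everywhere; this is the
documented boundary mode. Smoothing applies to GMV only.

**pALFF.** For each in-mask voxel the raw ratio is the summed periodogram
power over FFT bins with $0.01 \le f \le 0.08$ Hz (closed interval at the
FFT's natural grid, no interpolation) divided by the summed power over all
positive-frequency bins up to Nyquist ($1/(2\,\mathrm{TR})$; 0.303 Hz at
TR 1.65 s). The map is then divided by its mean within the brain mask, so
the masked mean is exactly 1. Numerical choices, all toggleable:

* *Power, not amplitude*: "power spectrum" is taken literally as the
  squared FFT magnitude; `use_amplitude = TRUE` reproduces the classic
  ALFF-style amplitude sum.
* *Linear detrend on, DC bin excluded* by default — otherwise scanner
  drift dominates the denominator.
* Rectangular-window periodogram on the full series (no Welch
  segmentation), scaled so total power equals the time-domain sum of
  squares (Parseval), which the tests assert.
* All-zero series get raw ratio 0 with a warning; an empty mask is an
  error.

The raw ratio is scale-invariant, so any multiplicative calibration of the
BOLD signal cancels.

## What the synthetic generators emulate — and what they do not

The generator defaults *are* the study conditions and are not adjusted per
analysis:

* **Ages** come from a two-component Gaussian mixture, components
  (30, 7) and (67, 8) years with weights 0.45/0.55, clipped to [20, 80] —
  a bimodal lifespan cohort thin in middle age. The exact mixture shape is
  a package choice; only bimodality and the range are externally given.
* **Memory**: standardized WM and STM are linear in standardized age with
  slopes −0.61 and −0.54, residuals correlated at 0.4 (the two tasks tap
  overlapping systems), marginal variance 1. Raw scores are mapped to the
  published test scales (WM 107.96 ± 13.88; STM 26.17 ± 6.39).
* **Trials**: 24 per condition. Relative-clause RTs are lognormal — RTs
  are positive and right-skewed — with meanlog/sdlog moment-matched to the
  target per-condition mean and SD across participants (OR 2.89 ± 1.28 s,
  SR 2.43 ± 0.99 s), a within-participant trial sd of 0.35 on the log
  scale, and a participant-level slowing term that grows with age,
  slightly steeper for OR (0.115 vs 0.10 log-units per SD of age). Those
  slopes were chosen once so that the age–RT and age–rtSDS correlations
  sit near the weak levels typical of healthy cohorts (≈ +0.25 and −0.2);
  condition means are recentered against the drawn cohort so the expected
  cohort mean hits the target exactly, while SDs are matched by moment
  approximation (the tests check means to Monte-Carlo precision and SDs to
  a few percent).
* **Accuracy**: Bernoulli per trial at the condition target (OR 86.6%,
  SR 89.7%), shifted on the logit scale by 0.25 × standardized WM plus an
  idiosyncratic participant offset (SD 0.3); the intercept is re-solved on
  the drawn cohort so the mean accuracy is exact. The age–accuracy link
  therefore runs entirely through WM, mirroring a mediated effect.
* **Education, TIV, sex**: the source cohort reports only means/SDs or
  nothing; the discrete education distribution (levels 1–6, mean ≈ 5.1),
  the TIV parameters (1400/1550 ± 110 mL by sex), and their independence
  from memory are invented and flagged as such.
* **ROI features**: baseline 0.7 units with −0.002 units/year of age and
  noise SD 0.05, giving the strong negative age correlations typical of
  gray matter. Planted ROIs instead receive an exact standardized
  construction: $M = a\,\mathrm{age}_z + \sqrt{1-a^2}\,e$, and the chosen
  outcome column is rewritten as a unit-variance blend of its original
  values and the $e$ residuals, making the population partial coefficient
  of $M$ in $Y \sim X + M$ exactly $b$. Ground truth ($a$, $b$, $ab$) is
  recorded for recovery tests.
* **Phantom**: three labeled blocks containing a 0.05 Hz sinusoid, a
  0.20 Hz sinusoid, and white noise (per-voxel random phase, configurable
  noise floor), 427 volumes at TR 1.65 s by default.

Deliberately *not* emulated: BOLD autocorrelation and physiological noise,
cortical geometry and spatial correlation between ROIs, item-level
psycholinguistic effects beyond condition and age, practice/priming
effects, and any direct age path to accuracy outside memory. Passing the
recovery tests therefore demonstrates that the statistical machinery is
correct and calibrated under clean conditions — not that real imaging data
meet these assumptions.

A single master seed feeds per-generator streams (`derive_seed`), so
cohorts, trials, features, and phantoms can be regenerated independently
and all outputs are bit-identical under a fixed seed.

## Numerical and design notes

* Degenerate inputs: constant vectors are rejected by `standardize()`;
  zero-SD conditions exclude nobody in the outlier rule; rank-deficient
  mediation designs error with the collinear columns named.
* A strictly noise-free chain $X = M$, $Y = M$ is collinear by
  construction and is rejected rather than fit; the unit-path behavior is
  verified on a numerically full-rank chain with negligible noise.
* The bisquare tuning constant 4.685 (95% Gaussian efficiency) and the
  MAD-based scale are the field's standard choices and are exposed as
  arguments.
* Covariates are z-scored once for conditioning; this cannot change the
  standardized paths, which the equivariance tests confirm.
* Test and simulation problem sizes (e.g. calibration at $n = 5000$;
  bootstrap calibration at $B = 500$ with 200–500 replicates; ROI recovery
  at $n = 300$, $B = 1000$, 50 replicates with the OLS estimator) were
  chosen to give stable Monte-Carlo estimates at desk scale; the full
  robust pipeline at $B = 5000$ is the intended analysis setting.

## Known limitations

* The BC p-value is defined by CI inversion; other toolboxes use direct
  formulas that can differ in the third decimal.
* Only single-mediator models are supported — no multiple mediators,
  moderated mediation, or latent-variable SEM — and no causal
  identification diagnostics are provided: a "significant mediator" is a
  model statement, not a causal certificate.
* pALFF here consumes minimally prepared series (no motion correction or
  nuisance regression); those belong upstream.
* FDR families are fixed at hemisphere × modality; other groupings are a
  one-line change on the result table but are not the default.

## A minimal run

```{r, eval = FALSE}
library(roimediate)

cfg <- synthetic_config(
  n_participants = 300, seed = 42,
  planted_rois = data.frame(roi = "L_pSTG", a = -0.45, b = 0.35))
sim <- simulate_study(cfg)
rf <- generate_roi_features(sim$cohort, sim$truth, cfg, outcome = "rt_sds")

cfgA <- analysis_config("rt_sds", modality = "GMV", n_boot = 1000,
                        expected_sign_ab = "-", seed = 42)
tab <- run_roi_mediation(rf$cohort, rf$features, cfgA)
tab[tab$significant, c("roi", "beta_ab", "p_ab", "p_ab_fdr")]

map <- write_stat_map(atlas, tab, "t_indirect")  # given an atlas_volume
write_volume(map, "indirect_tstat.nii.gz")
```
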