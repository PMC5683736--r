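---
title: "Staging myocardial fibrosis in aortic stenosis from T1-mapping ECV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging myocardial fibrosis in aortic stenosis from T1-mapping ECV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrostage)
```

## The problem and the model

Pressure overload from aortic stenosis drives left-ventricular hypertrophy
that decompensates in two histological steps: diffuse interstitial fibrosis
(expansion of the extracellular matrix throughout the myocardium) and, later,
irreversible replacement scar. Cardiac MRI sees both: diffuse fibrosis through
contrast-enhanced T1 mapping, replacement scar as mid-wall late gadolinium
enhancement (LGE). This package implements a staging of that transition built
on three quantities per subject:

* **Partition coefficient** `lambda = dR1_myo / dR1_blood`, where
  `dR1 = 1/T1_post - 1/T1_native` is the contrast-induced change in the
  relaxation rate, averaged over the analysable mid-cavity segments.
* **ECV fraction** `ECV = lambda * (1 - Hct)`: the extracellular fraction of
  myocardial tissue volume, using the haematocrit to convert the blood-pool
  signal to a plasma reference.
* **Indexed extracellular volume**
  `iECV = ECV * (LV mass / 1.05) / BSA` (ml/m^2): the *total* extracellular
  compartment of the left ventricle normalised to body size. ECV fraction
  alone overlaps heavily between health and disease because hypertrophy grows
  the cellular compartment in step; multiplying by myocardial volume restores
  the discrimination.

Staging is control-anchored: the upper limit of normal is the healthy-arm
mean + 2 SD of iECV (with the reference control statistics 16.1 +/- 3.2
ml/m^2 this is 22.5 ml/m^2), and each patient is classified by the hierarchy

1. infarct-pattern LGE anywhere → excluded from the diffuse-fibrosis analysis
   (the scar is ischaemic, not part of the hypertrophic transition);
2. no computable metrics (incomplete T1 data) → unclassified;
3. mid-wall LGE → **replacement fibrosis**, regardless of iECV;
4. iECV at or above the threshold → **extracellular expansion**;
5. otherwise → **normal myocardium**.

Downstream, the package computes stage-wise crude mortality rates per 1,000
patient-years, Kaplan-Meier curves and the K-group log-rank test (all written
out from first principles so they are oracle-testable), plus the group
comparison and regression utilities used around the staging result.

## Conventions and numerical choices

* **Formulas for lambda and ECV** are the standard delta-R1-ratio and
  `lambda * (1 - Hct)` definitions of the T1-mapping literature; they are the
  only formulation consistent with paired values such as lambda 0.45 with ECV
  26.5% at Hct ~0.41.
* **Segment averaging** takes the arithmetic mean of segmental T1 *before*
  conversion to R1 (one region copied between native and post-contrast maps),
  not the mean of per-segment lambdas.
* **Segment inclusion**: mid-wall-LGE segments are included (diffuse change in
  the remote myocardium is still informative), infarct-pattern segments are
  excluded; a patient with any infarct-pattern LGE is excluded from staging
  even if some segments are usable.
* **Myocardial density** 1.05 g/ml converts LV mass to end-diastolic
  myocardial volume; exposed as the `density` argument everywhere.
* **Threshold boundary**: a patient exactly at the threshold is staged as
  expansion (the rule is `>=`). The SD uses the n - 1 sample denominator, the
  convention for reference ranges.
* **Reporting precision**: 1 d.p. for iECV, integer percentages, both with
  half-up rounding (`round_half_up()`), matching clinical-table conventions;
  base R's `round()` would use banker's rounding.
* **Haematocrit** is a per-subject input. Whether a same-day measured or a
  synthetic haematocrit should feed the ECV computation is left to the user;
  the package does not guess.
* **Tie convention in survival**: deaths precede censorings at equal times.
  The log-rank statistic uses the hypergeometric variance with a generalised
  inverse fallback for singular variance matrices; p-values come from the
  chi-square reference (a permutation oracle is kept in the tests).
* **Cause-specific mortality** treats non-AS deaths as censorings (naive
  cause-specific rates); no competing-risks estimator is provided because the
  downstream report needs none.
* **Regression fits** (logistic IRLS, OLS via QR) are implemented in the
  package so they can be checked against closed forms and likelihood grids;
  `glm`/`lm` appear only as independent cross-checks in the test suite.
  Perfect separation in the logistic fit is detected (diverging coefficients
  with fitted probabilities at 0/1) and raised as an error.
* **Tertile stratification** places boundaries at the empirical 1/3 and 2/3
  points with lower-boundary-inclusive assignment, so 161 distinct values
  split 54/54/53 and ties always collapse downward; degenerate boundaries
  warn. No trend-specific test is attached: the per-variable K-group test is
  reported and the choice of a dedicated trend test is documented as open.
* **No multiple-testing correction** is applied; results follow the two-sided
  p < 0.05 convention of the clinical analysis this mirrors.

## What the synthetic cohort emulates

There is no public subject-level dataset for this analysis, so the package
carries a generator (`generate_cohort()`) whose *defaults are the study
conditions*: 37 controls and 166 patients, latent stages mixed as
71/31/37 classifiable patients plus 22 infarct-pattern exclusions and 5 with
incomplete T1 mapping, severity (mild/moderate/severe) drawn conditional on
stage, and follow-up with exponential event times at stage hazards
0.008/0.036/0.071 per person-year under uniform administrative censoring over
1.3-4.5 years (mean 2.9, SD ~0.9 years).

Design points worth knowing:

* **Generation is inverted relative to observation.** The latent stage is
  drawn first; iECV is then drawn from the stage-wise distributions
  (Normal 18.3 +/- 2.5, 25.4 +/- 3.1, 30.4 +/- 8.2 ml/m^2; controls
  16.1 +/- 3.2), truncated at the 22.5 anchor for the normal (above) and
  expansion (below) stages so that staging against the anchor threshold can
  recover the latent stage exactly. This inversion is what makes the
  round-trip test possible at all.
* **The T1 panel is solved backward.** ECV is drawn per stage (~26.5/27.5/
  29.1%), LV mass index follows as `iECV * 1.05 / ECV` (landing on the
  73/96/107 g/m^2 pattern — the published group means are internally
  consistent under this inversion), lambda follows from ECV and haematocrit,
  and the post-contrast segmental T1 mean is solved from lambda given the
  drawn native and blood-pool T1s. Segment-level jitter is re-centred so the
  usable-segment means are exact; `compute_ecv_metrics()` therefore recovers
  the latent iECV to ~1e-14.
* **Calibration is analytic, not tuned.** Truncation shifts the stage means
  (the expansion mean rises to ~26.4), so the iECV mean of the
  infarct-excluded group is solved at config-build time (closed-form
  truncated-normal means + uniroot) to make the population mean over AS
  patients with computable metrics exactly 23.6 ml/m^2.
* **Distributions are truncated Gaussians** (or log-normals for biomarkers)
  at physiologic bounds; only means/SDs/medians are anchored by published
  summaries, so all higher moments are conventions. Haematocrit is
  Normal(0.41, 0.03) on [0.25, 0.55]; blood-pool T1s (~1880 native, ~450 ms
  post) are field-typical values, not published ones.
* **The biopsy link** maps iECV to histological %fibrosis linearly
  (intercept 1.015, slope 0.4326, Gaussian noise SD 1.76, clamped to
  [0, 100]). The line passes through the biopsy-subtable anchors
  (iECV 18.8/25.6/49.6 → 8.9/12.4/22.4%), and the noise SD puts the implied
  population Pearson correlation over the AS-arm iECV spread in the 0.87
  regime. A linear link cannot simultaneously match the whole-cohort stage
  means and the biopsy-subtable means; the subtable is the anchor because it
  is what the histological validation measured.
* **Seeding**: one master integer seed; per-subject streams are derived from
  it, so a cohort is byte-identical across runs and the record for subject i
  does not depend on how later subjects are configured.

What the generator does *not* emulate: imaging noise and segmentation error
(metrics are exact by construction), correlation between iECV and follow-up
beyond the stage mixture, multi-site batch effects, and non-exponential
hazards. Passing tests therefore demonstrate the correctness of the analysis
machinery and the internal consistency of the published summaries — not
robustness to measurement error in real cohorts.

## Problem sizes used in validation

The arm-mean and rate-recovery checks use ~5,000 subjects per arm or stage
(sampling error ~3 SE bands with Poisson SEs for rates); the biopsy sampling
distribution uses 400 draws of n = 11 from a 5,000-patient arm; the log-rank
permutation oracle enumerates all relabelings of fixtures with n <= 10. These
sizes make Monte-Carlo error small relative to every tolerance tested while
keeping a full run in the order of a minute or two.

## A worked run

```{r example, eval = FALSE}
cfg <- cohort_config(seed = 20260101)   # the default study conditions
cohort <- generate_cohort(cfg)
fit <- fibrosis_staging(cohort)         # threshold derived from the controls
summary(fit)                            # stage table, iECV means, outcomes
out <- stage_outcomes(fit)
out$table                               # deaths, person-years, rates /1,000 py
run_pipeline(cfg, "run1")               # full artifact set + manifest
```

## Known limitations

* Crude rates on a 166-patient cohort carry wide Poisson error; the package
  reproduces published-scale rates only under large simulated cohorts.
* The chi-square reference for the log-rank test is approximate at very small
  n; the tests document a 0.15 agreement band against the exhaustive
  permutation null at n = 10.
* `fit_logistic()` offers Wald intervals only (no profile likelihood), which
  is adequate away from separation but optimistic near it.
* The LVH reference (age/sex 95th-percentile LV-mass lookup) is consumed as a
  user-supplied table, not shipped.
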