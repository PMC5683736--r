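# fibrostage

Staging myocardial fibrosis in aortic stenosis from cardiac-MRI T1 mapping.

Aortic stenosis drives left-ventricular hypertrophy that decompensates through
diffuse interstitial fibrosis into irreversible replacement scar. `fibrostage`
implements the CMR analysis of that transition for researchers working with
ROI-level T1-mapping data: per-subject extracellular-volume metrics, a
control-anchored staging rule, and the stage-wise outcome statistics — plus a
calibrated synthetic cohort generator so the whole pipeline is reproducible
and testable without patient data.

## The model

For each subject, from six mid-cavity segments with native and ~20-min
post-contrast myocardial T1, a blood-pool T1 pair and the haematocrit:

```
lambda = (1/T1_myo_post  - 1/T1_myo_native) /
         (1/T1_blood_post - 1/T1_blood_native)      (partition coefficient)
ECV    = lambda * (1 - Hct)                          (extracellular fraction)
iECV   = ECV * (LV mass / 1.05 g/ml) / BSA           (ml/m^2, Du Bois BSA)
```

Segments with infarct-pattern LGE are excluded from the average; mid-wall-LGE
segments are kept. The upper limit of normal is the healthy-control
mean + 2 SD of iECV (22.5 ml/m^2 at the reference control statistics
16.1 ± 3.2 ml/m^2), and patients are staged by the hierarchy: infarct-pattern
LGE → excluded; no computable metrics → unclassified; mid-wall LGE →
**replacement fibrosis**; iECV ≥ threshold → **extracellular expansion**;
otherwise → **normal myocardium**. Stage-wise outcomes use crude mortality
rates per 1,000 patient-years, Kaplan-Meier curves, and the K-group log-rank
test, all implemented in the package.

## Worked example

```r
library(fibrostage)

cfg    <- cohort_config()            # default: 37 controls + 166 AS patients
cohort <- generate_cohort(cfg)       # seeded synthetic cohort
fit    <- fibrosis_staging(cohort)   # threshold derived from the control arm
summary(fit)
```

```
Fibrosis staging of 166 AS patients against 37 controls
iECV upper limit of normal: 22.6 ml/m2 (control mean 16.3 + 2 SD x 3.1, n = 37)
  normal myocardium        75 (55%)
  extracellular expansion  30 (22%)
  replacement fibrosis     31 (23%)
  excluded: infarct LGE n = 25, incomplete T1 n = 5

Stage-wise iECV (ml/m2):
  normal       n =  75  18.1 +/- 2.2
  expansion    n =  30  25.6 +/- 2.1
  replacement  n =  31  30.5 +/- 7.6

Outcomes by group (7 deaths in total)
       group  n deaths person_years rate_per_1000py as_deaths as_rate_per_1000py
      normal 75      0        223.5             0.0         0                0.0
   expansion 30      1         84.8            11.8         1               11.8
 replacement 31      6         73.9            81.2         5               67.6
All-cause: Log-rank test: chi-square = 19.36 on 2 df, p = 6.259e-05
```

Reading this: the derived threshold (22.6 ml/m^2 on this random control arm)
sits by construction near the 22.5 reference; the three stages split roughly
half / quarter / quarter of classifiable patients with strictly increasing
iECV; and mortality climbs steeply across stages — on a 166-patient cohort the
rates are noisy (7 deaths here), which is why calibration checks use
simulated cohorts of thousands.

Other entry points: `compute_ecv_metrics()` / `compute_cohort_metrics()` for
the metric chain alone, `predict(fit, newdata)` to classify new subjects with
a fitted threshold, `stage_outcomes()` / `km_fit()` / `logrank_test()` for
the survival layer, `summarize_groups()`, `tertile_stratify()`,
`correlate()`, `fit_logistic()`, `fit_linear()` for the cohort statistics,
and `run_pipeline()` (or `inst/scripts/run_pipeline.R`) for an end-to-end run
that writes cohort/metrics/staged/outcome CSVs and a reproducibility
manifest.

See `vignettes/fibrosis-staging.Rmd` for the full account of the model,
the generator's calibration, and the numerical conventions.

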