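# glycorr

HbA1c reflects glucose exposure accumulated over the life of the red blood
cell, so any process that shortens mean RBC lifespan mechanically lowers
measured HbA1c at a given glycemia. In type 2 diabetes this produces
systematic underestimation of glycemic burden — and of complication risk — in
the sizeable fraction of patients whose RBC lifespan falls below 90 days.

`glycorr` is an R package for clinicians and biostatisticians working with
cohorts that carry HbA1c, average glucose (AG), and RBC lifespan (from the
endogenous-CO breath test). It provides:

- **Formula layer** — estimated HbA1c from AG via the ADAG relation
  `eHbA1c = (AG + 2.5944)/1.5944` (mmol/L); the hemoglobin glycation index
  `HGI = HbA1c − eHbA1c`; RBC lifespan from a CO breath sample
  (`lifespan = k_cal · [Hb] / net alveolar CO`); lifespan grouping
  (SHORT ≤ 66 d, MID 67–89 d, NORMAL ≥ 90 d); and the published piecewise
  correction
  - `HbA1c(c) = −0.05629·lifespan + 1.127·HbA1c + 3.178` (≤ 66 d),
  - `HbA1c(c) = −0.004772·lifespan + 0.7569·HbA1c + 2.394` (67–89 d),
  - identity for ≥ 90 d.
- **Model building** — SSE-optimal hinge breakpoint detection on the
  HGI–lifespan relation (with a restricted-cubic-spline curve for plotting),
  subgroup OLS fitting of eHbA1c on (lifespan, HbA1c), Spearman,
  Kruskal–Wallis and chi-square statistics, odds ratios with Woolf intervals.
- **Validation** — ROC AUC (Mann–Whitney, DeLong or bootstrap CI), threshold
  metrics, and quantile-bin calibration for the outcome eHbA1c > 7%.
- **Synthetic cohorts** — a seeded generator reproducing the statistical
  structure the analysis assumes (three lifespan strata, group-model-driven
  eHbA1c, elevated complication odds below 90 days), so the whole pipeline is
  testable without patient data.
- **Pipeline & CLI** — simulate or load cohorts, 4:1 construction/internal
  split, fit, apply, validate, with a deterministic output tree
  (`inst/cli/glycorr` exposes `simulate`, `metrics`, `fit`, `correct`,
  `validate`, `run-all`).

## Worked example

```r
library(glycorr)

# Correct a single measurement: HbA1c 7.0% at lifespan 60 and 80 days
correct_hba1c(7.0, c(60, 80, 100))
#> [1] 7.6896 7.3105 7.0000
# 7.0% measured at a 60-day lifespan corresponds to a corrected 7.69% —
# above the usual 7% control target even though the raw value sits at it.

# Full study replica on a simulated 516-patient hospital cohort
cfg <- pipeline_config(cohort_config = cohort_config(n_patients = 516,
                                                     seed = 20260911))
res <- run_pipeline(cfg)

res$proportions
#>    group   n   pct
#> 1  SHORT  92 22.12
#> 2    MID 122 29.33
#> 3 NORMAL 202 48.56
res$inflection$inflection_days
#> [1] 69
res$fitted_models$SHORT
#> <correction_model SHORT> HbA1c(c) = -0.0474515*lifespan +1.14341*HbA1c +2.61491  (R = 0.9736)
res$summary[, c("cohort_label", "n", "auc", "calibration_slope")]
#>              cohort_label   n       auc calibration_slope
#> construction construction 416 0.9835796         0.9863115
#> internal         internal 100 0.9915697         1.0002527
#> independent   independent 165 0.9930821         0.9980074
```

About half the simulated patients have a lifespan under 90 days; the
breakpoint search recovers the generating 66-day inflection to within a few
days at this sample size; the construction-cohort fit recovers coefficients
near the generating (published) ones, exactly so when the generator noise is
set to zero; and the corrected HbA1c discriminates poor glycemic management
(eHbA1c > 7%) with AUC ≈ 0.98 on these well-specified synthetic cohorts
(higher than on real data, where eHbA1c is not generated from the model
being validated).

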