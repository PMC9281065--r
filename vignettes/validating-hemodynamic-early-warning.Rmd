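---
title: "Validating hemodynamic-instability early-warning scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating hemodynamic-instability early-warning scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemodyn)
library(dplyr)
```

## The problem

Roughly one in five mixed-ICU patients deteriorates to the point of needing
circulatory support — vasoactive drugs, large-volume fluid resuscitation, or
blood transfusion. Multi-parameter machine-learning risk scores promise
earlier warning than single indicators such as systolic blood pressure (SBP)
or the shock index (heart rate / SBP), but a score developed at one site
must be validated externally before it can be trusted at another: outcome
incidence, predictor effects, and above all the *case mix* (the distribution
of predictor values) differ between hospitals.

`hemodyn` packages the machinery of such an external validation so it can be
rerun, end to end, on any conforming data — or on a bundled synthetic cohort
whose ground truth is known, so that every stage of the machinery is
testable against closed-form expectations.

The outcome is operationalized from intervention logs, not diagnoses: a
patient becomes "unstable" at the first qualifying hemodynamic intervention.
Because intervention logs are the label source, the validation hinges on
getting the annotation rules, the time alignment (hours before onset), and
the evaluation statistics exactly right; those are the parts this package
treats as first-class, tested code.

## The pipeline

1. **Annotation** (`annotate_cohort()`): detect instability onsets from
   intervention records under a named ruleset, build unstable segments, and
   partition patients into stable / unstable / excluded.
2. **Feature extraction** (`build_sample_matrix()`): plausibility-filter the
   observation stream, sample all 33 registry variables at hourly reference
   times (1–24 h before onset for unstable patients; a single 5-h
   post-admission sample for stable patients), and impute.
3. **Scoring** (`train_risk_model()`, `predict_risk()`): a retrainable
   gradient-boosted tree ensemble standing in for any proprietary score; the
   validation harness accepts any scorer that maps samples to probabilities.
4. **Evaluation** (`delong_ci()`, `time_varying_auroc()`,
   `threshold_sweep()`, `lead_time_analysis()`, `calibration_table()`,
   `subgroup_metrics()`, `case_mix_report()`).

`run_pipeline()` sequences all stages deterministically from one seed.

## Annotation rules

Two rulesets are built in (`ruleset("TPEVGH")`, `ruleset("US")`). Both share:

* **Vasoactive**: any administration, of any quantity, of dobutamine,
  dopamine, epinephrine, norepinephrine, phenylephrine or vasopressin.
  Brand synonyms (Levophed, Neosynephrine) normalize through an editable
  dictionary file; unrecognized agents map to a sentinel and never trigger.
* **Fluid therapy**: cumulative crystalloid/colloid volume reaching
  2400 cc within 8 h, or 3000 cc within 12 h.

They differ on blood products: the TPEVGH column adds 25% albumin
(≥ 200 cc / 2 h), PRBC strictly greater than 1500 cc / 24 h, and the
combination PRBC 500 + FFP 500 + platelet pheresis 500 cc within 6 h; the US
column instead uses PRBC ≥ 800 cc / 24 h and PRBC ≥ 500 cc / 2 h followed by
fluid therapy within 12 h (onset reported at the PRBC crossing).

Comparators follow the printed wording verbatim: "2400 cc in 8 h" is read as
*reaching* the dosage (≥), "PRBC > 1500 cc" as strictly exceeding it. The
package asserts both readings in its tests (exactly 2400 cc triggers;
exactly 1500 cc does not).

### Numerical conventions

* **Window convention.** Cumulative volumes are evaluated over the
  half-open look-back window `(t − W, t]`, at event times only: charted
  boluses are point masses, so a crossing can only happen when a record is
  charted. Continuous infusions must be discretized by the caller.
* **Re-arming.** After a crossing, detection re-arms only once the running
  window total falls back below the threshold, so one sustained episode
  yields one onset. The window total changes at event times (up) and event
  expiries (down); both are walked. The exact published segment-merging
  rule is not reproducible from the main text, so this re-arm rule and the
  segment merge gap (`merge_gap_h`, default 1 h — the scoring interval) are
  explicit, configurable stand-ins.
* **First-segment rule.** Only the first segment beginning more than 6 h
  after ICU admission is used for validation. Patients whose *only*
  segments begin at or before 6 h are **excluded**, not called stable: they
  did receive interventions, and counting them as negatives would
  contaminate the stable class. (The source material is ambiguous here;
  this is the package's declared choice.)
* **Inclusion.** Age strictly greater than 20 years, length of stay at
  least 6 h, and a non-empty observation profile.

## The feature registry

The 33 variables (vitals including invasive and noninvasive pressures,
chemistry and hematology labs, blood gases, ventilation settings) live in an
editable CSV with literature-standard plausibility ranges; out-of-range
values are nulled, never clipped. The published variable table and
imputation method are supplementary-only, so the shipped registry is an
explicit stand-in a site can replace. One adjustment was needed to keep the
registry at exactly 33 entries: ALT is omitted (AST is the transaminase the
validation literature discusses).

Sampling uses last-observation-carried-forward with per-variable staleness
limits — vitals 4 h, ventilation settings 8 h, labs and blood gases 48 h —
after which a value is treated as missing rather than stale. Two clinical
fallbacks run after LOCF, in a fixed order (filter, then LOCF, then
fallback): missing invasive systolic/diastolic/mean pressures are filled
from the same-row noninvasive counterpart, and missing FiO₂ is set to the
room-air fraction 0.21. Everything else stays missing; the tree ensemble
handles missingness natively through learned default branches, so no
statistical imputation is performed. Observed values are never overwritten,
and ties at one timestamp resolve last-written-wins.

Stable patients contribute one sample at admission + 5 h by default. The
alarm analyses need stable scores over time, so `build_sample_matrix()` has
an hourly stable mode (`stable_hourly = TRUE`) used for the false-alarm
rate.

## The risk score stand-in

The published score is an ensemble of interpretable decision trees whose
trained weights are proprietary; this package therefore ships a
*retrainable stand-in* — gradient-boosted, depth-limited trees (xgboost;
200 trees, depth 4, learning rate 0.1 by default) with native
missing-value branch handling — and never claims to reproduce the original
weights. What the package does reproduce is the validation harness around
any conforming scorer: `predict_risk()` is a pure function of (model, row),
and any vector of probabilities can be fed to the evaluation functions.

Training draws one random lead-time row per unstable patient (seeded) plus
the stable rows, mimicking onset-anchored training without leaking a
patient's full pre-onset trajectory; rows are canonically sorted before
fitting so the model is invariant to input row order, and train/test splits
are by patient, never by row.

## Evaluation statistics

* **AUROC** uses the Mann–Whitney formulation with midranks (ties count
  one half); it is cross-checked in the tests against exhaustive pair
  counting.
* **DeLong** variance and covariance come from the structural components
  (computed via midranks), giving normal-approximation CIs truncated to
  [0, 1] and the paired test for correlated AUROCs. With perfect
  separation the variance degenerates and the CI collapses to the point,
  flagged rather than hidden. Coverage is verified by simulation against
  the Gaussian closed form.
* **Time-varying AUROC** compares unstable rows at each lead 1–24 h
  against the stable rows; the single stable sample is reused at every
  lead (matching one-shot stable extraction), with the hourly stable mode
  available for sensitivity analysis.
* **Alarms** fire when `score > threshold`, strictly. The default
  threshold is fixed at 0.7 — the operating point chosen in the validation
  this package generalizes — with break-even and recall-constrained
  policies available in `select_threshold()`.
* **Lead time**: the first alarm is the *earliest* crossing in clock time
  within the 24 h window, i.e. the largest alarmed lead; the cumulative
  curve `fraction(first alarm ≥ k hours early)` is non-increasing by
  construction. The false-alarm rate is the fraction of stable
  patient-hours above threshold.
* **Calibration** uses equal-width probability bins (deciles of
  probability, not of sample mass); empty bins are reported with zero
  count.
* **Case mix**: per-variable cohort medians and percent difference
  `(B − A)/A`, Kruskal–Wallis for continuous baseline characteristics,
  Fisher's exact test for categorical ones. Subgroup and baseline p-values
  are reported raw, uncorrected, as is conventional in validation reports.
  Year-by-year slices merge a sparse final year into its predecessor
  (`year_groups()`).

## The synthetic cohort

`generate_cohort()` emulates the *structure* of a single-center EHR
extract, not its physiology:

* ~19% of patients are destined to receive a qualifying intervention
  (configurable prevalence).
* Each patient carries a latent severity `z`: `N(0, 1)` for stable,
  `N(d, 1)` for destined-unstable patients (`d` = 1.5 by default).
* Each variable's expression of `z` is a signed drift in SD units, with
  directions matching the documented group differences: blood pressures,
  hemoglobin and hematocrit fall; heart rate, CVP, BUN, lactate, AST,
  creatinine, airway pressures and FiO₂ rise. Stable patients express
  their severity at a constant level; unstable patients ramp linearly over
  the 24 h deterioration horizon, reaching full magnitude one hour before
  onset — so the last scored pre-onset sample carries the full latent
  separation and the best achievable lead-1 AUROC equals the closed form
  `theoretical_auroc(d) = pnorm(d / sqrt(2))`, while discrimination decays
  toward 0.5 at the horizon. Per-patient baseline offsets (0.5 SD) and
  per-observation noise (0.8 SD) sit on top.
* Sampling frequencies and missingness are realistic per category (vitals
  hourly, ventilation 4-hourly, blood gases 8-hourly, labs daily; lactate
  missing at 22.1% per scheduled sample, invasive pressures at 35% to
  exercise the noninvasive fallback).
* Destined-unstable patients get an intervention bundle that satisfies
  exactly one criterion at the true onset, rotating among a vasoactive
  dose, 3 × 800 cc boluses over 4 h, 2 × 800 cc PRBC over 6 h, and the
  500/500/500 cc transfusion combination, plus post-onset vasoactive
  continuation that merges into the same segment. Onsets are drawn
  log-normal (median 24 h) with a 7 h floor so every generated onset
  survives the first-segment rule. Stable patients optionally receive
  sub-threshold 500 cc fluid distractors (at most two, so no window can
  reach 2400 cc) to keep the annotation task non-trivial.
* One global seed fans out to per-patient substreams keyed by patient id,
  so generating a smaller cohort leaves the shared patients' draws
  byte-identical, and all values are clamped inside the registry
  plausibility ranges (the filter is a no-op on clean synthetic data).

What the generator does **not** emulate: mechanistic cardiovascular
dynamics, inter-variable correlation beyond the one shared latent signal,
informative missingness, treatment feedback after onset, or the case-mix
idiosyncrasies of any real hospital. Passing tests on this cohort
demonstrate that the *machinery* — annotation, alignment, statistics — is
correct, not that any particular score will attain a particular AUROC on
real patients.

## A worked run

```{r pipeline, eval = FALSE}
run <- run_pipeline(pipeline_config(n_patients = 2000, seed = 1))
glance(run)
run$evaluation$discrimination$model        # AUROC + DeLong CI at lead 1
autoplot(run$evaluation$time_varying)      # AUROC by hours before onset
autoplot(run$evaluation$lead_time)         # first-alarm lead distribution
autoplot(run$evaluation$calibration)
```

At these conditions (2000 patients, d = 1.5, half the patients held out)
the held-out lead-1 AUROC of the retrained ensemble lands within ±0.05 of
the closed-form ceiling `pnorm(1.5 / sqrt(2)) ≈ 0.856`, and the time-varying
curve decays monotonically in trend toward 0.5 at 24 h — both are asserted
in the test suite. The default problem sizes (2000-patient cohorts for the
closed-form check, 500-patient cohorts over five seeds for the annotation
round trip, 500 replicates for the DeLong coverage simulation) were chosen
to keep Monte-Carlo error well below the tolerances being checked.

## Known limitations

* The annotation segment rules beyond the published criteria (merge gap,
  re-arming) are declared stand-ins, configurable but not verifiable
  against the original supplementary material.
* The registry's plausibility bounds and staleness limits are
  literature-standard defaults, not the original site's table.
* The stand-in learner's operating characteristics (e.g. where raw scores
  sit relative to a fixed 0.7 threshold) depend on the training recipe and
  class balance; threshold-dependent quantities on synthetic data are
  exercised as machinery, not calibrated to any published operating point.
* Evaluation treats each patient's validation segment as one event; repeat
  instability episodes within a stay are annotated but not evaluated.
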