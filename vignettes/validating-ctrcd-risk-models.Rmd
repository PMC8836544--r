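---
title: "Validating CTRCD risk models against serial LVEF surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating CTRCD risk models against serial LVEF surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctrcdval)
```

## Scope and procedure

Trastuzumab-treated HER2-positive breast cancer patients undergo serial left
ventricular ejection fraction (LVEF) surveillance because a minority develop
cancer-therapy-related cardiac dysfunction (CTRCD). Several baseline risk
models exist to stratify patients before therapy — the Ezaz et al. points
model, the NSABP B-31 cardiac risk score (CRS) of Romond et al., and the
HFA-ICOS trastuzumab proforma — but a score is only useful if its categories
separate patients by *observed* event rates in cohorts outside the derivation
data.

`ctrcdval` implements that external-validation procedure end to end:

1. **Cohort ingestion** (`read_cohort()`, `apply_inclusion_filter()`): a
   baseline-covariate table plus a long table of serial LVEF studies, with
   schema and invariant checks that report offending rows, and an inclusion
   rule requiring a pre-therapy (time 0) study and a configurable number of
   follow-ups (default 3, matching common surveillance practice of
   roughly-quarterly studies over a year of therapy).
2. **Risk scoring** (`score_cohort()`): a declarative engine that evaluates
   YAML model configurations of three archetypes — summed points
   (`points_sum`), a continuous formula with cutpoints (`formula`), and
   ordinal risk-level combination (`level_combination`). Three
   configurations ship with the package (see "Shipped configurations").
3. **Outcome adjudication** (`adjudicate_cohort()`): rule-based CTRCD calls
   from the LVEF series under the CREC, ESC, or ASE definitions.
4. **Statistics** (`run_validation()` and its components): incidence by
   category, between-category association tests, discrimination (AUC with
   DeLong confidence intervals), calibration of predicted versus observed
   risk, and relative risks of extreme categories.
5. **Synthetic cohorts** (`generate_cohort()`): a seeded generator whose
   defaults emulate the covariate marginals of a 629-patient validation
   cohort, used for end-to-end testing and power exploration.

## CTRCD definitions and adjudication decisions

The three supported definitions differ in drop threshold, strictness, and
the absolute LVEF floor:

| Definition | Asymptomatic rule          | Symptomatic rule       | Comparison |
|------------|----------------------------|------------------------|------------|
| CREC       | drop ≥ 10 points to < 55%  | drop ≥ 5 points to < 55% | inclusive (≥) |
| ESC        | drop > 10 points to < 50%  | —                      | strict (>) |
| ASE        | drop > 10 points to < 53%  | —                      | strict (>) |

Each patient's baseline is the earliest study (under
`modality_policy = "same_modality_only"`, the earliest study *per modality*,
and drops are only computed within modality — echocardiographic and MUGA
LVEF are not interchangeable; `"pooled"` compares across modalities). Two
adjudication decisions deserve explanation because the published definitions
leave them open:

* **Baselines already below the lower limit of normal (LLN).** A patient
  whose baseline LVEF is below the LLN cannot "fall below the floor" in the
  usual sense. We give the strict > 10-point-drop branch precedence for such
  patients: any subsequent drop exceeding 10 points is an event regardless
  of the floor. This is the conservative reading that avoids making
  low-baseline patients unadjudicable.
* **LLN defaults to the definition's floor.** Users can supply an
  institutional LLN via `ctrcd_definition(name, lln = ...)`; when they do
  not, the LLN is taken to be the definition's own floor (55 for CREC, 50
  for ESC, 53 for ASE), so the below-LLN branch engages exactly where the
  definition stops being able to fire through its main branch.

Within a visit, the asymptomatic criterion takes precedence over the
symptomatic one when both are met, so a ≥ 10-point symptomatic drop is
recorded under the larger-threshold criterion.

## Shipped configurations are structural placeholders

The three YAML files under `inst/extdata/models/` encode the *structure* of
the published models — their covariates, category logic, and combination
rules — with placeholder weights clearly marked as such in the files. They
exercise every feature of the scoring engine (points with age bands, a
monotone linear formula with tertile cutpoints and a spline risk function,
and ordinal level combination with optional biomarker factors). Users
validating the published models should transcribe the authoritative weights
from the original publications into copies of these files; the engine, not
the numbers, is the deliverable.

The HFA-ICOS combination rule implemented is: any very-high factor →
very-high; otherwise any high factor, or ≥ 5 medium factors → high;
otherwise 2–4 medium factors → medium; otherwise low. Biomarker factors
(troponin > 16 ng/L, BNP > 100 pg/mL) only participate when
`include_biomarkers = TRUE`, because biomarkers are frequently unmeasured
and would otherwise render most patients unscorable.

## Statistical choices

* **Association tests** use the Pearson chi-square **without** continuity
  correction by default (`association_test(..., method = "chi_square")`);
  `"fisher"` and `"auto"` (Fisher when any expected cell < 5) are available.
  The uncorrected Pearson statistic is the standard choice for r × 2
  incidence tables of this size and reproduces the conventional reporting in
  the field.
* **AUC and its confidence interval** are computed in-package: the
  Mann-Whitney estimator with half-credit for ties, with the DeLong variance
  from case/control placements. This is part of the validated surface and is
  oracle-tested against exhaustive pair counting (and cross-checked against
  pROC in the test suite).
* **Calibration points** are per-category observed rates with Wald logit
  confidence intervals from an intercept-only binomial GLM, falling back to
  Clopper-Pearson intervals (flagged as such) when a category has zero or
  only events, where the Wald interval degenerates.
* **The CRS risk function** is a restricted cubic spline fit to published
  anchor points, built on the natural-spline basis (`splines::ns`) with
  boundary knots at the outermost knots, solved by least squares, with
  predictions clipped to [0, 1]. The test suite verifies it against an
  independent truncated-power-basis implementation solved via the normal
  equations.
* **Tertile stratification** uses type-7 sample quantiles with ties at a
  cutpoint assigned to the lower group, and flags degenerate stratifications
  (collapsed cutpoints) rather than failing silently.
* **Formula-model categories in `run_validation()`** default to
  *cohort-derived tertiles* (`formula_categories = "tertiles"`) rather than
  the configuration's fixed cutpoints, because external validation
  conventionally re-derives tertiles in the validation cohort; pass
  `"config"` to use the shipped cutpoints instead.

## What the synthetic generator emulates — and what it does not

`generator_config()` defaults encode the covariate marginals of the emulated
629-patient cohort: age 52.4 ± 10.9 (truncated to [19, 90]), baseline LVEF
64 ± 7% (truncated to [40, 85]), cumulative anthracycline 272.4 ± 76 mg/m²,
stage I/II/III = 20/52/28%, MUGA 70%, hypertension 18%, diabetes 7%,
coronary artery disease 3%, heart failure history 1%, anthracycline exposure
90%, and so on. These defaults *are* the emulated study conditions, not
tuning knobs.

Covariates are drawn **independently** — only marginals, not a joint
distribution, are available for the emulated cohort. A `correlate` hook lets
users inject dependence. The event process is the package's own stand-in: a
logistic model on standardised covariates whose intercept is the logit of
the target marginal rate (default `qlogis(0.24)`), with default
coefficients chosen to be clinically plausible in sign and ordering
(hypertension, diabetes, coronary disease, prior heart failure, and
anthracycline exposure raise risk; higher baseline LVEF lowers it). Event
patients receive, at one uniformly chosen follow-up, an LVEF drop sized to
satisfy the configured CTRCD definition with a configurable severity margin;
non-event visits fluctuate around baseline with 2.5-point test-retest noise.

The generator does **not** emulate: real LVEF trajectory shapes (recovery,
transient dips), informative censoring or missed visits, inter-modality
systematic offsets, or treatment interruption. It is a fidelity instrument
for the validation machinery — `recover_category_gradient()` demonstrates
the intended use: a configuration whose event-model coefficients load on a
model's risk factors should produce observed incidence that is
non-decreasing across that model's categories up to Monte-Carlo noise.

Cohort sizes used in the package's own checks (5,000–20,000 synthetic
patients; 10,000 random trajectories for definition-nesting tests) are the
package's own choices, sized so that Monte-Carlo error is small relative to
the effects under test while the full suite still runs in seconds.

## A worked run

```{r example}
gen <- generate_cohort(generator_config(n_patients = 2000, seed = 42))
report <- run_validation(
  gen$cohort,
  models = c("ezaz", "nsabp31_crs", "hfa_icos_trastuzumab"),
  definitions = "CREC"
)
print(report)
```

Published incidence tables for a 629-patient external validation cohort are
available via `validation_cohort_tables()` for direct reanalysis:

```{r tables}
tabs <- validation_cohort_tables()
association_test(tabs$hfa_icos, "chi_square")
relative_risk(tabs$hfa_icos, "high", "low")
```
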