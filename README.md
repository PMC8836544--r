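# ctrcdval

External validation of baseline cardiotoxicity risk models against serial
LVEF surveillance in trastuzumab-treated breast cancer.

## Why

Trastuzumab substantially improves outcomes in HER2-positive breast cancer,
but a minority of patients develop cancer-therapy-related cardiac
dysfunction (CTRCD), detected through serial left ventricular ejection
fraction (LVEF) surveillance. Several baseline risk models exist to
stratify patients *before* therapy — the Ezaz et al. points model, the
NSABP B-31 cardiac risk score (CRS) of Romond et al., and the HFA-ICOS
trastuzumab proforma — yet a model is only clinically useful if its risk
categories separate patients by observed event rates in cohorts outside the
data that built it.

`ctrcdval` implements that external-validation workflow end to end:

- **Cohort I/O and invariants** — CSV ingestion of a baseline-covariate
  table plus a long serial-LVEF table, with row-level error reporting and
  an inclusion filter (pre-therapy study + configurable minimum follow-up).
- **Declarative risk scoring** — a YAML-driven engine supporting summed
  points, continuous formulas with cutpoints and a spline risk function,
  and ordinal level-combination models. Structural configurations of the
  three models above ship in `inst/extdata/models/` (placeholder weights,
  clearly marked; transcribe authoritative weights from the original
  publications for clinical use).
- **CTRCD adjudication** — rule-based calls from serial LVEF under the
  CREC, ESC, and ASE definitions, with same-modality or pooled baseline
  policies and a skip log for unadjudicable series.
- **Validation statistics** — incidence tables, Pearson chi-square (no
  continuity correction) and Fisher tests, AUC with DeLong confidence
  intervals, calibration with Wald-logit/Clopper-Pearson intervals,
  one-way ANOVA, and relative risks; `run_validation()` orchestrates all
  model × definition pairs into a single report.
- **Synthetic cohorts** — a fully seeded generator whose defaults emulate
  the covariate marginals of a 629-patient validation cohort, with a
  logistic event model and guaranteed-detectable LVEF drops, for testing
  and power exploration.
- **CLI** — `riskval_main()` (and the `inst/cli/riskval.R` wrapper) with
  `synth`, `adjudicate`, and `validate` subcommands.

## Worked example

Incidence tables from a 629-patient external validation cohort ship with
the package:

```r
library(ctrcdval)
tabs <- validation_cohort_tables()
tabs$hfa_icos
#>   category n_total n_events percent
#>        low     193       30   15.5%
#>     medium     404      109   27.0%
#>       high      27       10   37.0%
#>  very_high       5        2   40.0%

association_test(tabs$hfa_icos, "chi_square")$p_value
#> [1] 0.00521354
relative_risk(tabs$hfa_icos, "high", "low")
#> [1] 2.382716
```

The full pipeline on a synthetic cohort:

```r
gen <- generate_cohort(generator_config(n_patients = 2000, seed = 42))
run_validation(gen$cohort,
               models = c("ezaz", "nsabp31_crs", "hfa_icos_trastuzumab"),
               definitions = "CREC")
#> <validation_report> 2000 patients, 3 model x definition pairs
#>
#> == ezaz / CREC (n = 2000 scored, 0 unscorable)
#>  category n_total n_events percent
#>       low    1724      377   21.9%
#>    medium     261       71   27.2%
#>      high      15        4   26.7%
#>    chi_square p = 0.147
#>    AUC (categories) 0.52 (95% CI 0.50-0.54)
#>
#> == nsabp31_crs / CREC (n = 2000 scored, 0 unscorable)
#>  category n_total n_events percent
#>       low     667      100   15.0%
#>    medium     666      141   21.2%
#>      high     667      211   31.6%
#>    chi_square p = 1.91e-12
#>    AUC (categories) 0.61 (95% CI 0.58-0.63)
#>    AUC (raw score)  0.62 (95% CI 0.60-0.65)
#>
#> == hfa_icos_trastuzumab / CREC (n = 2000 scored, 0 unscorable)
#>   category n_total n_events percent
#>        low    1075      199   18.5%
#>     medium     787      210   26.7%
#>       high     115       35   30.4%
#>  very_high      23        8   34.8%
#>    chi_square p = 2.8e-05
#>    AUC (categories) 0.57 (95% CI 0.54-0.59)
```

Adjudication of a single patient's series:

```r
series <- data.frame(patient_id = "P1", time = c(0, 90, 180),
                     lvef = c(65, 62, 54), modality = "MUGA")
adjudicate(series, ctrcd_definition("CREC"))$event
#> [1] TRUE   # 11-point drop to below 55%
```

See `vignettes/validating-ctrcd-risk-models.Rmd` for the methods:
definition semantics (including below-LLN baselines and the LLN default),
the HFA-ICOS combination rule, statistical choices, and exactly what the
synthetic generator does and does not emulate.

## License

MIT
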