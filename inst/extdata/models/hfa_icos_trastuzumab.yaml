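# HFA-ICOS baseline risk proforma for trastuzumab-containing therapy:
# patient and treatment factors carry a level (medium / high / very_high)
# and the triggered levels combine into one final category.
#
# Factor levels follow the published trastuzumab proforma where the main
# text states them; verify the full list against the HFA-ICOS position
# paper before clinical use. Biomarker thresholds are institutional upper
# reference limits (hsTnI > 16 ng/L, BNP > 100 pg/mL); the biomarker
# factors only fire when scoring is run with include_biomarkers = TRUE.
model_id: hfa_icos_trastuzumab
label: HFA-ICOS trastuzumab risk proforma
combination: level_combination
factors:
  - {field: heart_failure_history, op: is_true, level: very_high,
     label: "prior heart failure or cardiomyopathy"}
  - {field: baseline_lvef, op: "<", value: 50, level: high,
     label: "baseline LVEF < 50%"}
  - {field: baseline_lvef, op: between, value: [50, 54.999], level: medium,
     label: "borderline baseline LVEF 50-54%"}
  - {field: age, op: ">=", value: 80, level: high, label: "age >= 80"}
  - {field: age, op: between, value: [65, 79.999], level: medium,
     label: "age 65-79"}
  - {field: coronary_artery_disease, op: is_true, level: high,
     label: "coronary artery disease"}
  - {field: atrial_fibrillation, op: is_true, level: medium,
     label: "atrial fibrillation"}
  - {field: hypertension, op: is_true, level: medium, label: "hypertension"}
  - {field: diabetes, op: is_true, level: medium, label: "diabetes mellitus"}
  - {field: current_smoker, op: is_true, level: medium,
     label: "current smoker"}
  - {field: anthracycline_received, op: is_true, level: medium,
     label: "prior anthracycline exposure"}
  - {field: troponin, op: ">", value: 16, level: medium, biomarker: true,
     label: "elevated baseline troponin"}
  - {field: bnp, op: ">", value: 100, level: medium, biomarker: true,
     label: "elevated baseline BNP"}
# Combination rule (config-overridable; verify against the HFA-ICOS position
# paper): any very_high factor -> very_high; else any high factor or >= 5
# medium factors -> high; else 2-4 medium factors -> medium; else low.
combination_rule:
  medium_min: 2
  high_medium_min: 5
category_labels: [low, medium, high, very_high]
# Band representatives for calibration: the published bands are low < 2%,
# medium 2-9%, high 10-19%, very high > 20%; 30% is used as the very-high
# representative.
predicted_risk:
  low: 0.01
  medium: 0.055
  high: 0.145
  very_high: 0.30
metadata: >
  Engine-native encoding of the expert-consensus trastuzumab proforma;
  combination rule shipped as a concrete default because the proforma
  publishes factor levels, not an algebraic rule.
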