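# Points-based 3-year heart-failure / cardiomyopathy risk model for older
# women with HER2+ breast cancer on adjuvant trastuzumab (Ezaz et al.,
# SEER-Medicare derivation). Total points run 0 (lowest) to 12 (highest);
# only the aggregated categories (0-3 low, 4-5 medium, 6-9+ high) carry
# published incidences.
#
# PLACEHOLDER POINT ALLOCATIONS: the exact published point table lives in the
# original publication and is not transcribed here. The factor list below
# uses the model's covariates on the same 0-12 scale and is editable; verify
# against Ezaz et al. before any clinical use.
model_id: ezaz
label: Points-based HF/cardiomyopathy risk model (SEER-Medicare derivation)
combination: points_sum
factors:
  - {field: anthracycline_received, op: is_true, points: 2}
  - {field: age, op: between, value: [75, 79.999], points: 1}
  - {field: age, op: ">=", value: 80, points: 2}
  - {field: coronary_artery_disease, op: is_true, points: 2}
  - {field: atrial_fibrillation, op: is_true, points: 2}
  - {field: diabetes, op: is_true, points: 2}
  - {field: hypertension, op: is_true, points: 1}
  - {field: heart_failure_history, op: is_true, points: 2}
categories:
  - {label: low, min: 0, max: 3}
  - {label: medium, min: 4, max: 5}
  - {label: high, min: 6, max: 14}
# Predicted risks = per-category event incidences reported in the source
# publication's derivation cohort. PLACEHOLDER transcription; verify against
# the source before clinical use.
predicted_risk:
  low: 0.165
  medium: 0.26
  high: 0.395
metadata: >
  Engine-native encoding of the published points model; point values and
  per-category incidences are marked placeholders pending transcription from
  the source publication.
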