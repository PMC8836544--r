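# NSABP B-31 cardiac risk score (CRS): a continuous score in age (years) and
# baseline LVEF (percent), developed in women treated with sequential
# anthracycline and trastuzumab (Romond et al.).
#
# PLACEHOLDER FORMULA: the published closed form lives in the source
# publication's appendix and is not transcribed here. The stand-in below is
# increasing in age and decreasing in baseline LVEF (the documented
# directions) and lands on the same numeric scale as the printed tertile
# cutpoints (<= 50 / 51-64 / >= 65 in a 629-patient external validation
# cohort). Edit in place once the published coefficients are transcribed.
model_id: nsabp31_crs
label: NSABP B-31 cardiac risk score
combination: formula
formula: "age + 0.9 * (65 - baseline_lvef)"
required_fields: [age, baseline_lvef]
monotone:
  age: increasing
  baseline_lvef: decreasing
# Score <= 50 -> low; 50 < score <= 64 -> medium; score > 64 -> high
# (ties at a cutpoint go to the lower group).
cutpoints: [50, 64]
category_labels: [low, medium, high]
# Anchors for the CRS -> cardiac-event-risk function, read off the source
# publication's cumulative-incidence figure. PLACEHOLDER values (the figure
# has not been transcribed); monotone and deliberately low-risk, as the
# derivation-cohort event rates were far below typical external CTRCD rates.
risk_function:
  anchors:
    - [30, 0.005]
    - [40, 0.010]
    - [50, 0.018]
    - [60, 0.032]
    - [70, 0.055]
    - [80, 0.090]
    - [90, 0.140]
  knots: [40, 55, 70, 85]
metadata: >
  Formula and risk-function anchors are editable placeholders pending
  transcription from the source publication.
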