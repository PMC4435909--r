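# Cambridge risk score: logistic model on age, sex, BMI band, family
# history, smoking, antihypertensive and corticosteroid treatment.
# SYNTHETIC coefficients: the predictor structure follows the published
# model; the numeric values below are illustrative stand-ins, not a
# transcription of the published equation. Replace before real use.
name: cambridge
source_ref: "Cambridge risk score (synthetic stand-in coefficients)"
synthetic_coefficients: true
link: logistic
intercept: -6.9
terms:
  - variable: age
    transform: identity
    coefficient: 0.063
  - variable: sex
    transform: categorical
    levels:
      female: -0.40
  - variable: bmi
    transform: binned
    cutpoints: [25.0, 27.5, 30.0]
    values: [0.0, 0.7, 1.5, 2.2]
  - variable: on_htn_meds
    transform: identity
    coefficient: 0.85
  - variable: fh_cat
    transform: categorical
    levels:
      parent_or_sibling: 0.70
      parent_and_sibling: 1.00
  - variable: smoker
    transform: identity
    coefficient: 0.60
  - variable: corticosteroids
    transform: identity
    coefficient: 1.20
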