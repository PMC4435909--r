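# Simplified Finnish risk score: point score on age band, sex, BMI band,
# antihypertensive treatment, family history, smoking and corticosteroid
# use, with a logistic score-to-logit calibration.
# SYNTHETIC point values and calibration: structure per the published
# model, values are illustrative stand-ins.
name: finnish_simplified
source_ref: "Simplified Finnish risk score (synthetic stand-in coefficients)"
synthetic_coefficients: true
link: logistic
intercept: 0.0
score_to_lp:
  intercept: -6.6
  slope: 0.40
terms:
  - variable: age
    transform: binned
    cutpoints: [45, 55, 65]
    values: [0, 2, 3, 4]
  - variable: sex
    transform: categorical
    levels:
      male: 1.0
  - variable: bmi
    transform: binned
    cutpoints: [25, 30]
    values: [0, 1, 3]
  - variable: on_htn_meds
    transform: identity
    coefficient: 2
  - variable: fh_cat
    transform: categorical
    levels:
      parent_or_sibling: 1.0
      parent_and_sibling: 2.0
  - variable: smoker
    transform: identity
    coefficient: 1
  - variable: corticosteroids
    transform: identity
    coefficient: 1
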