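# Rotterdam predictive model 1: point score on age, sex, BMI and
# antihypertensive treatment, with a logistic score-to-logit calibration.
# SYNTHETIC point values and calibration: structure per the published
# model, values are illustrative stand-ins.
name: rotterdam_1
source_ref: "Rotterdam predictive model 1 (synthetic stand-in coefficients)"
synthetic_coefficients: true
link: logistic
intercept: 0.0
score_to_lp:
  intercept: -4.2
  slope: 0.55
terms:
  - variable: age
    transform: binned
    cutpoints: [50, 60, 70]
    values: [0, 1, 2, 3]
  - variable: sex
    transform: categorical
    levels:
      male: 1.0
  - variable: bmi
    transform: binned
    cutpoints: [25, 30]
    values: [0, 1, 2]
  - variable: on_htn_meds
    transform: identity
    coefficient: 1
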