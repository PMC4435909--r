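# Omani diabetes risk score: integer point score on age, BMI, waist
# circumference, family history and blood pressure, mapped to a
# probability through a logistic score-to-logit calibration.
# SYNTHETIC point values and calibration: structure per the published
# model, values are illustrative stand-ins.
name: omani
source_ref: "Omani diabetes risk score (synthetic stand-in coefficients)"
synthetic_coefficients: true
link: logistic
intercept: 0.0
score_to_lp:
  intercept: -4.6
  slope: 0.33
terms:
  - variable: age
    transform: binned
    cutpoints: [35, 45, 55, 65]
    values: [0, 2, 3, 4, 5]
  - variable: bmi
    transform: binned
    cutpoints: [25, 30]
    values: [0, 1, 2]
  - variable: waist
    transform: binned
    cutpoints: [80, 90, 100]
    values: [0, 1, 2, 3]
  - variable: fh_any
    transform: identity
    coefficient: 2
  - variable: sbp
    transform: binned
    cutpoints: [130, 140]
    values: [0, 1, 2]
  - variable: dbp
    transform: binned
    cutpoints: [85, 90]
    values: [0, 1, 1]
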