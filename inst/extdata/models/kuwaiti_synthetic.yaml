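# Kuwaiti risk score: logistic model on age, antihypertensive treatment,
# family history and waist circumference.
# SYNTHETIC coefficients: structure per the published model, values are
# illustrative stand-ins.
name: kuwaiti
source_ref: "Kuwaiti risk score (synthetic stand-in coefficients)"
synthetic_coefficients: true
link: logistic
intercept: -7.6
terms:
  - variable: age
    transform: identity
    coefficient: 0.045
  - variable: on_htn_meds
    transform: identity
    coefficient: 0.80
  - variable: fh_any
    transform: identity
    coefficient: 0.90
  - variable: waist
    transform: identity
    coefficient: 0.028
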