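# Example end-to-end pipeline configuration: simulate the default synthetic
# cohort and analyse it under both hypertension criteria.
synthetic:
  "n": 20000     # quoted: a bare n is a YAML 1.1 boolean
  seed: 42
criteria: [chl2018, accaha2017]
k: 4
pattern:
  name: cardiometabolic
  members: [hypertension, diabetes, ami, angina, stroke_tia]
strata:
  - by: sex
  - by: age
    scheme: age_subgroup
  - by: ethnicity
min_stratum_n: 100
square_dissimilarity: false
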