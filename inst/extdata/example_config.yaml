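# Example run configuration for cgmscreen::run_compare().
# Omitted fields take the package defaults (the study-condition values).
seed: 2024

cohorts:
  births_per_cohort: 5000
  n_cohorts: 35
  max_follow_up_age: 100

onset:
  A: -0.0722
  B: 0.00118
  delta: 0.0952
  age_grid_min: 38
  age_grid_max: 92
  age_scale: 0.48
  adjustment: age-scale

growth:
  a: 0.8162
  b: 0.8162

detection:
  d0: 0.5

max_diameter: 120

scenarios:
  - name: optimal-early-biennial
    start_age: 30
    end_age: 65
    interval: 2
    attendance: imperfect
    sensitivity: moderate
  - name: iarc-biennial
    start_age: 50
    end_age: 69
    interval: 2
    attendance: imperfect
    sensitivity: moderate
  - name: iarc-biennial-high-sens
    start_age: 50
    end_age: 69
    interval: 2
    attendance: imperfect
    sensitivity: high
    perturb: 0.0
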