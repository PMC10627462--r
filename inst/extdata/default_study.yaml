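# Default pipeline configuration: the published study cohort.
# n = 384 startup managers/employees surveyed Aug-Sep 2021; 232 burnout
# cases; demographic cells consistent with the published gender, marital and
# children marginals; scale means and Pearson correlation calibration
# targets as published.
cohort:
  n_total: 384
  burnout_count: 232
  seed: 1
  calibrate: true
  demographic_cells:
    - {gender: female, marital_status: married, has_children: "yes", "n": 100}
    - {gender: female, marital_status: married, has_children: "no", "n": 33}
    - {gender: female, marital_status: single, has_children: "no", "n": 34}
    - {gender: male, marital_status: married, has_children: "yes", "n": 118}
    - {gender: male, marital_status: married, has_children: "no", "n": 13}
    - {gender: male, marital_status: single, has_children: "no", "n": 86}
  mean_targets:
    - {variable: age, gender: female, value: 40.43}
    - {variable: age, gender: male, value: 42.84}
    - {variable: job_experience, gender: female, value: 11.86}
    - {variable: job_experience, gender: male, value: 14.63}
    - {variable: covid_stress, gender: female, value: 8.00}
    - {variable: covid_stress, gender: male, value: 6.24}
    - {variable: resilience, gender: female, value: 11.86}
    - {variable: resilience, gender: male, value: 13.73}
    - {variable: exhaustion, value: 3.99}
    - {variable: cynicism, value: 3.72}
    - {variable: professional_efficiency, value: 2.97}
  correlation_targets:
    comp_exhaustion: 0.594
    comp_cynicism: 0.467
    comp_professional_efficiency: -0.322
    comp_resilience: -0.222
    stress_exhaustion: 0.532
    stress_cynicism: 0.427
    stress_professional_efficiency: -0.200
    stress_resilience: -0.306
fit:
  max_layers: 10
  neurons_kept: adaptive
  min_improvement: 1.0e-6
  ridge_epsilon: 1.0e-8
evaluation:
  K: 20
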