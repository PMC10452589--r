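schema: metasurv-config/1
costs:
  cea_test: 60.62
  clinic_visit: 25.94
  colonoscopy: 1059.35
  ct_scan: 300.15
  hepatic_metastasectomy: 4086.72
  post_anesthesia_recovery: 84.58
  palliative_chemo_month: 6409.77
  curative_chemo_month: 6409.77
utilities:
  ned: 0.78
  undetected_recurrence: 0.74
  curative_treatment: 0.74
  palliative_asymptomatic: 0.68
  palliative_symptomatic: 0.5
tests:
  clinic_visit:
    sensitivity: 0.42
    sensitivity_range:
    - 0.27
    - 0.57
    specificity: 0.95
    specificity_range:
    - 0.7
    - 1.0
  cea_test:
    sensitivity: 0.64
    sensitivity_range:
    - 0.49
    - 0.79
    specificity: 0.9
    specificity_range:
    - 0.75
    - 1.0
  ct:
    sensitivity: 0.83
    sensitivity_range:
    - 0.68
    - 0.98
    specificity: 0.93
    specificity_range:
    - 0.78
    - 1.0
  colonoscopy:
    sensitivity: 0.95
    sensitivity_range:
    - 0.8
    - 1.0
    specificity: 1.0
    specificity_range:
    - 0.85
    - 1.0
clinical:
  metastasectomy_mortality: 0.01
  metastasectomy_mortality_range:
  - 0.003
  - 0.015
  mean_months_undetected_to_symptomatic: 4.0
  mean_months_undetected_to_symptomatic_range:
  - 1.0
  - 28.0
  asymptomatic_metastasectomy_rate: 0.23
  symptomatic_metastasectomy_rate: 0.05
  curative_treatment_duration: 6.0
  palliative_chemo_duration: 1.0
  charge_false_positive_workup: yes
cohort:
  recurrence_fraction: 0.751
  median_followup_months: 76.4
  os5_recurred: 0.254
  os10_recurred: 0.031
  os10_nonrecurred: 0.815
settings:
  cycle_length: 1.0
  horizon: 120.0
  n_patients: 10000.0
  n_psa_draws: 10000.0
  n_patients_per_psa_draw: 1000.0
  annual_discount_rate: 0.015
  wtp_grid:
  - 0.0
  - 25000.0
  - 50000.0
  - 75000.0
  - 100000.0
  - 125000.0
  - 150000.0
  - 175000.0
  - 200000.0
  - 300000.0
  - 425000.0
  - 500000.0
  - 750000.0
  rng_seed: 17.0
psa:
  costs.clinic_visit:
    family: gamma
    mean: 25.94
    sd: 7.966836734694
  costs.colonoscopy:
    family: gamma
    mean: 1059.35
    sd: 3626.382653061225
  costs.hepatic_metastasectomy:
    family: gamma
    mean: 4086.72
    sd: 741.75
  costs.post_anesthesia_recovery:
    family: gamma
    mean: 84.58
    sd: 31.43
  clinical.metastasectomy_mortality:
    family: beta
    mean: 0.01
    sd: 0.00306122449
  clinical.mean_months_undetected_to_symptomatic:
    family: gamma
    mean: 4.0
    sd: 6.887755102041
  tests.clinic_visit.sensitivity:
    family: beta
    mean: 0.42
    sd: 0.076530612245
  tests.clinic_visit.specificity:
    family: beta
    mean: 0.95
    sd: 0.076530612245
  tests.cea_test.sensitivity:
    family: beta
    mean: 0.64
    sd: 0.076530612245
  tests.cea_test.specificity:
    family: beta
    mean: 0.9
    sd: 0.063775510204
  tests.ct.sensitivity:
    family: beta
    mean: 0.83
    sd: 0.076530612245
  tests.ct.specificity:
    family: beta
    mean: 0.93
    sd: 0.05612244898
  tests.colonoscopy.sensitivity:
    family: beta
    mean: 0.95
    sd: 0.051020408163
  tests.colonoscopy.specificity:
    family: beta
    mean: 1.0
    sd: 0.038265306122
  costs.cea_test:
    family: fixed
  costs.ct_scan:
    family: fixed
  costs.palliative_chemo_month:
    family: fixed
  costs.curative_chemo_month:
    family: fixed
  utilities.ned:
    family: fixed
  utilities.undetected_recurrence:
    family: fixed
  utilities.curative_treatment:
    family: fixed
  utilities.palliative_asymptomatic:
    family: fixed
  utilities.palliative_symptomatic:
    family: fixed
  clinical.asymptomatic_metastasectomy_rate:
    family: fixed
  clinical.symptomatic_metastasectomy_rate:
    family: fixed

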