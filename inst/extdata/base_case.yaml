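# Base-case configuration for the task-shifted CBT cost-benefit model.
# All monetary values are constant 2013 USD unless a year is stated.

economic_context:
  discount_rate: 0.03
  exchange_rate_kes_per_usd: 84.53
  reference_year: 2013
  cpi:
    2009: 100
    2010: 106.265
    2011: 121.17
    2013: 140.103

schedule:
  n_sites: 12
  # 160 participants per site in the first year, 240 in years 2-5
  # (12 x 160 + 12 x 240 x 4 = 13,440 participants in total)
  participants_per_site_by_year: [160, 240, 240, 240, 240]
  transport_kes_per_visit: 200
  visits_per_participant: 6

ledgers:
  training: training_costs.csv
  per_site: site_costs.csv

model:
  # 90-day abstinence rates, CBT arm vs usual care; their difference is
  # the abstinence effect (derived, 0.31)
  p_abst_cbt: 0.69
  p_abst_uc: 0.38
  # fraction of new HIV infections attributable to alcohol use
  alcohol_attrib_frac: 0.13
  # per-patient-year non-drug HIV treatment costs, 2009 USD
  nondrug_costs_2009:
    lab_tests: 32
    clinic_visits: 24
    support_services: 0.4
    fixed_costs: 32
  # 12-month tenofovir/3TC/EFV regimen, 2013 USD
  arv_drug_cost: 145.47
  # non-adherent / exposed counts; adherence gain is derived (0.19753)
  adherence_counts:
    hazardous: [19, 69]
    nondrinker: [112, 1439]
  # rise in weekly hours worked after ARV treatment, as a fraction of
  # baseline hours (+4.6 h on 24.3 h baseline, SE 1.88 h)
  lfp_rise: 0.19
  lfp_se_hours: 1.88
  lfp_baseline_hours: 24.3
  monthly_min_wage: 76.93
  # weekly household-productivity hour gains, females only
  hp_hours_firewood: 1.056
  hp_hours_water: 1.945
  hp_se_firewood: 0.461
  hp_se_water: 0.556
  # hourly minimum wage for a house worker, USD
  house_wage: 0.85
  female_fraction: 0.5
  effect_length: 2
  annualization_weeks: 48

# Uncertain inputs: one-way sensitivity ranges and the distribution family
# used in the probabilistic sensitivity analysis.
sensitivity:
  - name: delta_abstinence
    base: 0.31
    low: 0.21
    high: 0.41
    units: fraction
    distribution: uniform_range
  - name: alcohol_attrib_frac
    base: 0.13
    low: 0.018
    high: 0.165
    units: fraction
    distribution: uniform_range
  - name: lab_tests_2009
    base: 32
    low: 29.2
    high: 36.2
    units: 2009 USD/patient-year
    distribution: right_skewed_cost
  - name: clinic_visits_2009
    base: 24
    low: 18.8
    high: 29.2
    units: 2009 USD/patient-year
    distribution: right_skewed_cost
  - name: support_services_2009
    base: 0.4
    low: 0.10
    high: 0.90
    units: 2009 USD/patient-year
    distribution: right_skewed_cost
  - name: fixed_costs_2009
    base: 32
    low: 22.4
    high: 46.6
    units: 2009 USD/patient-year
    distribution: right_skewed_cost
  - name: arv_drug_cost
    base: 145.47
    low: 145.47
    high: 280.72
    units: 2013 USD/patient-year
    distribution: right_skewed_cost
  - name: monthly_min_wage
    base: 76.93
    low: 57.42
    high: 103.60
    units: USD/month
    distribution: uniform_range
  - name: lfp_rise
    base: 0.19
    low: 0.037
    high: 0.34
    units: fraction of baseline weekly hours
    distribution: normal_ci
    # CI reported on the hours scale; carried to the fraction scale
    se_hours: 1.88
    baseline_hours: 24.3
  - name: hp_hours_firewood
    base: 1.056
    low: 0.15
    high: 1.96
    units: h/week
    distribution: normal_ci
    se: 0.461
  - name: hp_hours_water
    base: 1.945
    low: 0.86
    high: 3.03
    units: h/week
    distribution: normal_ci
    se: 0.556
  - name: house_wage
    base: 0.85
    low: 0.58
    high: 1.03
    units: USD/hour
    distribution: uniform_range
  - name: adherence_gain
    base: 0.1975
    low: 0.1475
    high: 0.2475
    units: fraction
    distribution: uniform_range
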