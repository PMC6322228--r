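# Worked default scenario: colonoscopy surveillance of 50-year-old low-risk
# adenoma patients, 5-yearly (standard) vs 10-yearly (alternative) exams to
# age 75, 10-year cumulative CRC incidence 1% under the standard arm.
# Every field is optional; omitted fields keep these defaults.
schema_version: 1
p_S: 0.01
horizon_years: 10

standard:
  label: 5-yearly surveillance
  start_age: 50
  interval: 5
  stop_age: 75

alternative:
  label: 10-yearly surveillance
  start_age: 50
  interval: 10
  stop_age: 75

life:                      # Gompertz background mortality
  model: gompertz
  gompertz_a: 0.004        # hazard/yr at the reference age
  gompertz_b: 0.09         # log-hazard slope per year of age
  reference_age: 50

natural_history:
  baseline_rate: 0.001     # event hazard/yr at the reference age (pre-calibration)
  baseline_ref_age: 50
  doubling_time: 12        # years for the baseline hazard to double
  per_exam_protection: 0.5 # rho: hazard reduction during the protection window
  sensitivity_multiplier: 1.0
  excess_mortality_rate: 0.10  # /yr while diagnosed, for cure_horizon years
  cure_horizon: 5
  cycle_length: 0.0833333333333333  # 1 month
  horizon_age: 100
  discount_rate: 0

burden:
  anxiety_duration: 21     # days
  anxiety_disutility: 0.1
  procedure_duration: 2    # days
  procedure_disutility: 0.5
  complication_qaly_loss: 14        # days per non-fatal complication
  fatal_complication_probability: 0.0000333333333333333  # 1/30,000
  polypectomy_fraction: 0.3
  scaling: 1.0

complications:
  rate_at_40: 0.002
  rate_at_85: 0.038

treatment:                 # phase utility decrements (synthetic placeholders)
  initial: 0.30
  continuing: 0.10
  terminal: 0.45

econ:                      # unit costs are synthetic placeholders
  cost_per_colonoscopy: 885
  cost_per_complication: 10000
  cost_initial: 25000
  cost_continuing: 2500
  cost_terminal: 30000
  wtp: 20000

trial:
  p_S: 0.01
  alpha_one_sided: 0.05
  power: 0.90
  assumed_true_p_A: 0.01
  z_rounding: 3

sweep:
  disutility_scalings: [0.5, 0.8, 1.0, 1.2, 1.5]
  sensitivity_multipliers: [0.95, 1.0, 1.05]
  criterion: qaly
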