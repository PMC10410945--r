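# Aducanumab vs standard of care for mild Alzheimer's disease.
# Published annual transition probabilities, state costs (USD) and
# utilities; threshold = 3 x GDP per capita (WHO rule).
# The `conventions` block records the combination selected by
# calibrate_conventions() against the published base-case totals
# (see `calibration_targets`).
name: aducanumab-mild-alzheimer
states: [mild, moderate, severe, death]
absorbing: [death]
entry_state: mild
cohort_size: 1000
horizon: 5
transition_matrix:
  mild:     {mild: 0.774, moderate: 0.158, severe: 0.013, death: 0.055}
  moderate: {mild: 0.070, moderate: 0.501, severe: 0.214, death: 0.215}
  severe:   {mild: 0.001, moderate: 0.027, severe: 0.492, death: 0.480}
  death:    {mild: 0.000, moderate: 0.000, severe: 0.000, death: 1.000}
utilities: {mild: 0.73, moderate: 0.69, severe: 0.27, death: 0.0}
reference:
  name: SoC
  costs: {mild: 3140.0, moderate: 9460.0, severe: 16956.0, death: 0.0}
comparator:
  name: Aducanumab
  # drug price for the mild state; moderate/severe inherit SoC care costs
  costs: {mild: 22000.0, moderate: 9460.0, severe: 16956.0, death: 0.0}
  relative_risk: 0.6
  source_state: mild
conventions:
  rr_convention: complete_arrest
  reward_timing: begin
  apply_discount: no
  comparator_cost_mode: replace
discount:
  rate: 0.06
  range: [0.03, 0.09]
  first_cycle_undiscounted: yes
threshold:
  value: 28617.0
  gdp_per_capita: 9539.0
  multiplier: 3
psa:
  n_iterations: 1000
  uncertainty:
    cost: 0.2
    utility: 0.1
    transition: 0.1
ceac_grid: {from: 0, to: 150000, by: 500}
calibration_targets:
  reference_cost: 21292.16
  comparator_cost: 98068.49
  reference_qaly: 2.94
  comparator_qaly: 3.58
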