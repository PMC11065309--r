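# Base-case model inputs for the automated ward-monitoring cost-utility model.
# All monetary values are GBP at 2020/21 prices, stored at full precision;
# lifetime costs and QALEs are already discounted at the annual rate below.
probabilities:
  intervention:
    no_event: 0.9451
    event_survive: 0.0064
    inpatient_death: 0.0485
    dirichlet_counts: [3579.0, 24.0, 184.0]
  control:
    no_event: 0.9395
    event_survive: 0.0106
    inpatient_death: 0.0499
    dirichlet_counts: [3558.0, 40.0, 189.0]
principal_events:
  categories: [acute_myocardial_infarction, pulmonary_embolism,
    acute_pulmonary_oedema, respiratory_failure, severe_sepsis,
    icu_admission, cardiopulmonary_arrest]
  intervention:
    probability: [0.00000001, 0.00006559, 0.00004368, 0.00000000,
      0.00000001, 0.99989070, 0.00000001]
    concentration: [4.9231e-13, 0.0016, 0.0011, 3.6014e-13, 3.3553e-07,
      24.3621, 1.9882e-07]
  control:
    probability: [0.00000007, 0.00012726, 0.00002508, 0.00000012,
      0.19179070, 0.74615961, 0.06189716]
    concentration: [2.9955e-06, 0.0051, 0.0010, 4.9610e-06, 7.7047,
      29.9749, 2.4865]
lifetime:
  # use_no_event_cost: the no-event (ward-mix weighted) lifetime cost is
  # carried forward in place of this state's own cost.
  states:
    - name: ward1_gastroenterology
      lifetime_cost: 28694
      qale: 7.4965
      gamma: [25.0, 1147.75]
      normal: [7.50, 1.50]
      use_no_event_cost: false
    - name: ward2_respiratory
      lifetime_cost: 10555
      qale: 7.9866
      gamma: [25.0, 422.19]
      normal: [7.99, 1.60]
      use_no_event_cost: false
    - name: acute_myocardial_infarction
      lifetime_cost: 34398
      qale: 6.0139
      gamma: [25.0, 1375.91]
      normal: [6.01, 1.20]
      use_no_event_cost: false
    - name: pulmonary_embolism
      lifetime_cost: 19198
      qale: 6.9533
      gamma: [25.0, 767.92]
      normal: [6.95, 1.39]
      use_no_event_cost: true
    - name: acute_pulmonary_oedema
      lifetime_cost: 19198
      qale: 4.0633
      gamma: [25.0, 767.92]
      normal: [4.06, 0.81]
      use_no_event_cost: false
    - name: respiratory_failure
      lifetime_cost: 19198
      qale: 4.0633
      gamma: [25.0, 767.92]
      normal: [4.06, 0.81]
      use_no_event_cost: false
    - name: severe_sepsis
      lifetime_cost: 45903
      qale: 3.3345
      gamma: [25.0, 1836.14]
      normal: [3.33, 0.67]
      use_no_event_cost: false
    - name: icu_admission
      lifetime_cost: 19198
      qale: 4.0663
      gamma: [25.0, 767.92]
      normal: [4.06, 0.81]
      use_no_event_cost: false
    - name: cardiopulmonary_arrest
      lifetime_cost: 38303
      qale: 3.0013
      gamma: [25.0, 1532.14]
      normal: [3.00, 0.60]
      use_no_event_cost: false
resource_use:
  beds: 54
  mean_los_intervention: 8.62
  mean_los_control: 8.90
  cableless_rate: 0.123
  product_life: 5
  ward_mix_pulmonology: 0.56
  occupancy: 1.0
device_prices:
  fixed_intervention: 77448.61
  sensor_unit: 107.50
  fixed_control: 16800
episode_costs:
  intervention: {mean: 2046.99, low: 1926.45, high: 2183.47}
  control: {mean: 2059.16, low: 1957.03, high: 2174.21}
event_rates:
  intervention: {mean: 0.0666, low: 0.0543, high: 0.0786}
  control: {mean: 0.0933, low: 0.0743, high: 0.1114}
discounting:
  discount_rate: 0.035
  healthy_qale: 9.7732
  life_expectancy: 17.74
# Per-episode NHS activity unit costs (non-elective spell cost and cost per
# excess bed day). Informational inputs to episode costing; stroke and acute
# renal failure occur as episode-cost categories with zero discharge-state
# probability in the lifetime model.
unit_costs:
  ward1_gastroenterology: {non_elective: 1457, excess_bed_day: 259}
  ward2_respiratory: {non_elective: 1641, excess_bed_day: 230}
  acute_myocardial_infarction: {non_elective: 1592, excess_bed_day: 264}
  pulmonary_embolism: {non_elective: 1525, excess_bed_day: 230}
  acute_pulmonary_oedema: {non_elective: 1543, excess_bed_day: 230}
  respiratory_failure: {non_elective: 848, excess_bed_day: 230}
  stroke: {non_elective: 3609, excess_bed_day: 257}
  severe_sepsis: {non_elective: 2385, excess_bed_day: 239}
  acute_renal_failure: {non_elective: 1398, excess_bed_day: 239}
  icu_bed_day: {non_elective: 1620, excess_bed_day: .na}
  cardiopulmonary_arrest: {non_elective: 1628, excess_bed_day: 264}
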