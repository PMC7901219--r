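arms:
- label: ACTH
  summary:
    rr: 0.837
    os_median: 44.3
    ttp_median: 7.2
    dor_median: 5.6
    rp_digits: 3
  intervention_cost: 3112.0
  state_costs:
    stable: 8942.120000000001
    remission: 3129.74
    relapse: 19672.66
    death: 0.0
- label: TCH
  summary:
    rr: 0.704
    os_median: 35.0
    ttp_median: 10.35
    dor_median: 4.0
    rp_digits: 2
  intervention_cost: 1352.0
  state_costs:
    stable: 6419.31
    remission: 2246.76
    relapse: 14122.49
    death: 0.0
states:
- stable
- remission
- relapse
- death
utilities:
  stable: 0.74
  remission: 0.85
  relapse: 0.5
  death: 0.0
init:
  stable: 1.0
  remission: 0.0
  relapse: 0.0
  death: 0.0
n_cycles: 5
discount_rate: 0.05
half_cycle: yes
rounding: printed
constants:
  exit_factor: 0.75
  response_divisor: 3.0
thresholds:
  nmb_wtp: 34240.0
  ceac_wtp: 20000.0
  ceac_grid:
    from: 0.0
    to: 100000.0
    by: 2500.0
psa:
  n_sims: 1000
  fraction: 0.2
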