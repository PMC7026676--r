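# Hand-checkable miniature deck: two 6-month cycles,
# no discounting, a single 0.1/cycle other-cause death
# hazard from remission, remission utility 0.8.
# Expected totals: LY 0.95, QALYs 0.76.
deck_version: 1
econ:
  cycle_length: 0.5
  horizon: 2
  discount_rate: 0.0
  wtp_grid:
  - 0.0
  - 10000.0
  - 20000.0
  - 50000.0
  - 70000.0
  - 100000.0
  - 150000.0
  - 200000.0
cohort_size: 545
psa:
  iterations: 10000
  patients: 1000
strategies:
  AM:
    transitions:
      conversion_annual_year1: 0.0
      conversion_annual_later: 0.0
      salvage_split_pr: 0.5
      local_progression: 0.0
      metastasis: 0.0
      death_pc: 0.0
      death_other: 0.1
    costs:
      procedure: 0.0
      followup_per_cycle: 100.0
      salvage_pr: 0.0
      salvage_rt: 0.0
      metastatic_per_cycle: 0.0
    utilities:
      remission: 0.8
      salvage_pr: 0.5
      salvage_rt: 0.5
      metastatic: 0.5
    adverse_events: []
  PR:
    transitions:
      conversion_annual_year1: 0.0
      conversion_annual_later: 0.0
      salvage_split_pr: 0.5
      local_progression: 0.0
      metastasis: 0.0
      death_pc: 0.0
      death_other: 0.1
    costs:
      procedure: 0.0
      followup_per_cycle: 100.0
      salvage_pr: 0.0
      salvage_rt: 0.0
      metastatic_per_cycle: 0.0
    utilities:
      remission: 0.8
      salvage_pr: 0.5
      salvage_rt: 0.5
      metastatic: 0.5
    adverse_events: []
  RT:
    transitions:
      conversion_annual_year1: 0.0
      conversion_annual_later: 0.0
      salvage_split_pr: 0.5
      local_progression: 0.0
      metastasis: 0.0
      death_pc: 0.0
      death_other: 0.1
    costs:
      procedure: 0.0
      followup_per_cycle: 100.0
      salvage_pr: 0.0
      salvage_rt: 0.0
      metastatic_per_cycle: 0.0
    utilities:
      remission: 0.8
      salvage_pr: 0.5
      salvage_rt: 0.5
      metastatic: 0.5
    adverse_events: []

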