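# Default deck: published constants fixed at their source values;
# free parameters (per-strategy metastasis hazard, remission utility,
# AM follow-up cost per cycle, PR/RT procedure cost) calibrated by
# staged root-finding so the 10-year cohort run reproduces the
# published aggregates:
#   cost $15,654 / $18,791 / $30,378 (AM/PR/RT, discounted 3%/y)
#   life-years 9.54 / 9.57 / 9.57 (undiscounted)
#   QALYs 6.96 / 7.44 / 7.61 (undiscounted)
# Calibration tolerance 0.01 (relative); deterministic (no seed).
deck_version: 1
econ:
  cycle_length: 0.5
  horizon: 20
  discount_rate: 0.03
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
      conversion_annual_year1: 0.13
      conversion_annual_later: 0.05
      salvage_split_pr: 0.5
      local_progression: 0.0
      metastasis: 0.002726198242
      death_pc: 0.163339973466
      death_other: 0.003506146532
    costs:
      procedure: 0.0
      followup_per_cycle: 554.706688666049
      salvage_pr: 12000.0
      salvage_rt: 18000.0
      metastatic_per_cycle: 4000.0
    utilities:
      remission: 0.734671928014
      salvage_pr: 0.75
      salvage_rt: 0.73
      metastatic: 0.45
    adverse_events:
      incontinence:
        prob: 0.005
        cost: 2500.0
        decrement: 0.06
        window_cycles: 2.0
        duration_cycles: .inf
      sexual_dysfunction:
        prob: 0.026
        cost: 1200.0
        decrement: 0.05
        window_cycles: 2.0
        duration_cycles: .inf
      urinary_symptoms:
        prob: 0.025
        cost: 500.0
        decrement: 0.05
        window_cycles: 2.0
        duration_cycles: 1.0
  PR:
    transitions:
      conversion_annual_year1: 0.0
      conversion_annual_later: 0.0
      salvage_split_pr: 0.5
      local_progression: 0.005
      metastasis: 0.002108759303
      death_pc: 0.163339973466
      death_other: 0.003506146532
    costs:
      procedure: 12386.583023467691
      followup_per_cycle: 150.0
      salvage_pr: 12000.0
      salvage_rt: 18000.0
      metastatic_per_cycle: 4000.0
    utilities:
      remission: 0.832063935526
      salvage_pr: 0.75
      salvage_rt: 0.73
      metastatic: 0.45
    adverse_events:
      incontinence:
        prob: 0.22
        cost: 2500.0
        decrement: 0.06
        window_cycles: 2.0
        duration_cycles: .inf
      sexual_dysfunction:
        prob: 0.27
        cost: 1200.0
        decrement: 0.05
        window_cycles: 2.0
        duration_cycles: .inf
      urinary_symptoms:
        prob: 0.075
        cost: 500.0
        decrement: 0.05
        window_cycles: 2.0
        duration_cycles: 1.0
    surgical:
      prob: 0.1
      minor_weight: 0.666666666667
      major_weight: 0.333333333333
      window_cycles: 2.0
      minor:
        cost: 1200.0
        decrement: 0.03
        duration_cycles: 1.0
      major:
        cost: 7000.0
        decrement: 0.1
        duration_cycles: 2.0
  RT:
    transitions:
      conversion_annual_year1: 0.0
      conversion_annual_later: 0.0
      salvage_split_pr: 0.5
      local_progression: 0.005
      metastasis: 0.002108759303
      death_pc: 0.163339973466
      death_other: 0.003506146532
    costs:
      procedure: 25504.004886828709
      followup_per_cycle: 150.0
      salvage_pr: 12000.0
      salvage_rt: 18000.0
      metastatic_per_cycle: 4000.0
    utilities:
      remission: 0.823735020233
      salvage_pr: 0.75
      salvage_rt: 0.73
      metastatic: 0.45
    adverse_events:
      gi_long:
        prob: 0.036
        cost: 2000.0
        decrement: 0.04
        window_cycles: 2.0
        duration_cycles: .inf
      gi_short:
        prob: 0.025
        cost: 800.0
        decrement: 0.04
        window_cycles: 2.0
        duration_cycles: 1.0
      incontinence:
        prob: 0.003
        cost: 2500.0
        decrement: 0.06
        window_cycles: 2.0
        duration_cycles: .inf
      sexual_dysfunction:
        prob: 0.205
        cost: 1200.0
        decrement: 0.05
        window_cycles: 2.0
        duration_cycles: .inf
      urinary_symptoms:
        prob: 0.046
        cost: 500.0
        decrement: 0.05
        window_cycles: 2.0
        duration_cycles: 1.0

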