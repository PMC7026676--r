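# prostcea

Cost-effectiveness microsimulation of management strategies for
clinically localized prostate cancer.

Men aged 50–69 with newly diagnosed localized disease (T1–T2, NX, M0)
can be managed by active monitoring (AM), radical prostatectomy (PR),
or external-beam radiotherapy with neoadjuvant hormone therapy (RT).
Ten-year survival is nearly identical across the three, so the choice
turns on quality of life, treatment complications, and cost. This
package implements the decision model health economists use for that
question — a six-state Markov model (remission, local progression
salvaged with prostatectomy, local progression salvaged with
radiotherapy, metastatic disease, other-cause death, prostate-cancer
death) run in 6-month cycles over 10 years from the US payer
perspective — and the full analysis stack around it. It is written for
health-economics and outcomes researchers who want a reproducible,
scriptable version of the analysis rather than a point-and-click
decision tree.

## What it computes

For strategies indexed by *s*, with state occupancy evolved by
per-cycle transition matrices *P<sub>s,t</sub>*:

* mean **discounted cost** `C_s = Σ_t c_{s,t} (1.03)^(−t/2)` (costs at
  3%/year; one-time procedure/salvage/adverse-event costs booked when
  they occur), and mean **undiscounted** life-years `E_s` and QALYs
  (utility-weighted life-years, with additive adverse-event
  decrements);
* the **ICER** between strategies, `ΔC/ΔE`, the average **C/E** ratio,
  and the **net monetary benefit** `NMB(λ) = λE − C` at a
  willingness-to-pay threshold λ ($50,000/QALY by convention);
* the **cost-effectiveness frontier** with strong and extended
  dominance pruning;
* the **acceptability curve** (CEAC): the probability each strategy
  has the highest NMB across probabilistic sensitivity-analysis draws
  (beta/gamma parameter uncertainty, common random numbers across
  strategies);
* one-way (**tornado**) and follow-up-horizon sensitivity analyses.

Two engines share one expectation: a deterministic cohort engine
(exact state-distribution propagation) and a seeded patient-level
Monte Carlo microsimulation; the suite asserts their agreement. The
unpublished model inputs are recovered by `calibrate()`, which fits
nine free parameters (per strategy: metastasis hazard, remission
utility, one cost scalar) to the nine published 10-year aggregates by
staged monotone root-finding — see the methods vignette
(`vignettes/model-methods.Rmd`).

## Worked example

```r
library(prostcea)

deck <- deck_default()            # calibrated 10-year parameter deck
runs <- run_all(deck, "cohort")   # deterministic base case
runs$PR
#> <cea_run> PR, cohort mode
#>   discounted cost  $18791
#>   life-years       9.570
#>   QALYs            7.440

tab <- run_table(runs)
frontier(data.frame(strategy = tab$strategy, cost = tab$mean_cost,
                    effect = tab$mean_qaly), wtp = 50000)
#> <cea_table> at WTP $50,000 per effect unit
#>  strategy  cost effect dominance inc_cost inc_effect    icer    nmb ce_ratio
#>        AM 15654   6.96      none        0       0.00      NA 332346   2249.1
#>        PR 18791   7.44      none     3137       0.48  6535.4 353209   2525.7
#>        RT 30378   7.61      none    11587       0.17 68158.8 350122   3991.9

microsim_run(deck, "PR", n_patients = 5000, seed = 42)
#> <cea_run> PR, microsim mode (n = 5000, seed = 42)
#>   discounted cost  $18755 (SD 5594)
#>   life-years       9.541
#>   QALYs            7.422
```

Reading the frontier: none of the three strategies is dominated.
Moving from AM to PR buys 0.48 QALYs for $3,137 — an ICER of about
$6,500/QALY, far below the $50,000/QALY threshold, so PR is
cost-effective relative to AM. Moving from PR to RT buys a further
0.17 QALYs at about $68,000/QALY — above $50,000 but inside the range
some payers accept. At λ = $50,000 the NMB column ranks PR highest.
The microsimulation reproduces the cohort means within Monte Carlo
error and adds patient-level spread.

A command-line front-end (`exec/prostcea`) wraps the same functions:

```sh
prostcea cea  --deck inst/extdata/deck_default.yaml --out out/
prostcea ceac --deck inst/extdata/deck_default.yaml --seed 1 --out out/
```

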