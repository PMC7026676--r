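---
title: "Model structure, calibration and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, calibration and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prostcea)
```

## The decision problem

Men with newly diagnosed, clinically localized prostate cancer (T1–T2,
NX, M0; ages 50–69) face three management strategies with similar
10-year survival but very different side-effect profiles and costs:
active monitoring (AM), radical prostatectomy (PR), and external-beam
radiotherapy with neoadjuvant hormone therapy (RT). `prostcea`
implements a state-transition (Markov) model of this choice from the US
payer perspective: 6-month cycles over a 10-year horizon, costs
discounted at 3% per year, effectiveness measured in undiscounted
life-years (LY) and quality-adjusted life-years (QALYs).

## Health states and transitions

Six states: remission, local progression treated with salvage
prostatectomy, local progression treated with salvage radiotherapy,
metastatic disease, death from other causes, and death from prostate
cancer (the two deaths are absorbing). Transitions allowed each cycle:

* remission → salvage states: under AM this is dominated by *treatment
  conversion* — an annual probability of 13% in the first year and 5%
  in later years, converted to the 6-month cycle by the
  constant-hazard rule `1 − (1 − p)^0.5` and split between the two
  salvage routes (50/50 by default; the split is a deck parameter,
  since the evidence base reports conversions to "surgery or
  radiotherapy" without proportions). Under PR and RT a per-cycle
  local-progression probability plays the same role (recurrence
  requiring salvage).
* remission and salvage states → metastatic (per-cycle metastasis
  hazard, strategy-specific);
* metastatic → prostate-cancer death (per-cycle hazard);
* any alive state → other-cause death (per-cycle hazard, shared across
  states within a strategy; the cohort is demographically homogeneous).

All per-cycle probabilities are deck entries validated to lie in
[0, 1] with per-state exit mass at most 1.

## Accrual and discounting conventions

Membership at the *start* of a cycle accrues that cycle's amounts:
half a year of life, half a year times the state utility (minus active
adverse-event decrements, floored at zero) of QALYs, and the per-cycle
follow-up or metastatic-management cost. No half-cycle correction is
applied: the source analysis gives no indication of one, and the
convention is applied identically to all three strategies, so
incremental results are insensitive to it at these survival levels.
One-time costs are booked at the time they occur — the procedure at
t = 0, salvage treatment at the transition into a salvage state,
adverse-event costs at onset — and discounted by `(1.03)^(−t)` with t
in years at 6-month resolution. Costs are discounted; LY and QALYs are
deliberately *not* (the published base-case tables report them
undiscounted, and the ICERs mix discounted cost with undiscounted
effect; `frontier()` works on whatever cost/effect pairs it is given,
so fully discounted ICERs are available by passing discounted
effects).

## Adverse events

Each strategy carries its published first-year complication risks per
6-month cycle: PR 7.5% urinary symptoms, 22% incontinence, 27% sexual
dysfunction; AM 2.5%/0.5%/2.6%; RT 4.6%/0.3%/20.5% plus 2.5%
short-term and 3.6% long-term gastrointestinal problems. PR
additionally carries surgical complications split 2:1 minor:major; the
overall surgical-complication probability is not published and is set
once at 10% per cycle within the first-year window (a mid-range figure
for retropubic prostatectomy morbidity; it is a deck parameter).

Events occur at most once per patient, drawn per cycle during a
two-cycle (first treatment year) onset window. Acute events (urinary
symptoms, short-term GI, surgical complications) carry a one-time cost
and a utility decrement for a finite number of cycles; chronic events
(incontinence, sexual dysfunction, long-term GI) keep their decrement
from onset onward. Decrements are additive and the cycle utility is
floored at zero. With the shipped decks the floor never binds
(worst-case summed decrements are well below the smallest alive-state
utility), which is what makes the deterministic cohort expectation an
exact oracle for the microsimulation mean: event draws are independent
of the transition draws, so expectations factor through alive
occupancy.

## Two engines, one expectation

`cohort_run()` propagates the full state distribution by vector–matrix
products — a deterministic, exact expectation. `microsim_run()`
simulates individual patients by inverse-CDF draws against the same
transition rows. Each patient consumes a dedicated, pre-drawn block of
uniforms derived from the single explicit seed, so results are
bit-reproducible and invariant to patient execution order. The test
suite asserts agreement of the two engines within three standard
errors at 20,000 patients for every shipped deck and strategy; this is
the package's core correctness check, since the microsimulation and
the cohort engine share no accrual code path beyond the transition
matrix itself.

## Calibration: standing in for unpublished inputs

The published analysis prints its aggregate results but not its full
input tables. The package therefore treats nine quantities as *free*
parameters — per strategy: the metastasis hazard, the remission
utility, and one cost scalar (AM's per-cycle follow-up cost, since
monitoring has no up-front procedure; the procedure cost for PR and
RT) — and calibrates them so a fresh 10-year cohort run reproduces the
nine published aggregates (per-strategy discounted cost, LY, QALYs).

The fit is staged and triangular, which makes the inverse problem
well-posed with exactly as many targets as free parameters:

1. metastasis hazards → LY targets (costs and utilities cannot move
   survival);
2. remission utilities → QALY targets (utilities cannot move
   survival);
3. cost scalars → cost targets (costs feed back into nothing).

Each stage is a scalar, strictly monotone problem per strategy, so it
is solved by bracketed root-finding (`uniroot`) rather than a joint
least-squares fit — exact to tolerance, with no risk of a local
optimum, and roughly 40 model evaluations in total. Reported relative
errors always come from a fresh run of the fitted deck. Published
constants (complication probabilities, conversion rates, the 2:1
surgical split, economic settings) are never adjusted, and the test
suite asserts this by diffing the fixed paths.

The shipped `deck_default.yaml` is the template calibrated at
tolerance 0.01 (achieved ~1e-10); its provenance header records the
targets. Calibration recovers an *observationally equivalent* deck at
the printed aggregates, not the original study's inputs: quantities
the targets do not constrain (salvage-state utilities, metastatic
management cost, salvage costs, follow-up costs of PR/RT) are fixed at
mid-range placeholder values and absorbed by the free parameters. The
published follow-up-horizon cost trajectory is *not* fitted — the
source's own 10-year horizon-table costs disagree with its base-case
means, so the trajectory is reproduced qualitatively (the PR-vs-AM
ICER peaks at the shortest horizon and declines monotonically through
year 10, because PR's cost is front-loaded while AM accumulates
monitoring and conversion costs as its QALY deficit grows).

## The synthetic deck generator

`synth_deck()` draws complete decks with every published constant
fixed and every unpublished entry drawn uniformly from documented
plausible ranges (e.g. other-cause mortality 0.4–1.0%/year for men in
this age band; metastatic-state utility 0.35–0.55; PR procedure cost
$9,000–18,000 in 2008 Medicare terms). It emulates the *structure* of
the study's inputs, not their joint distribution: parameters are drawn
independently, costs are not skewed, and there are no age-specific
hazards. Passing tests on synthetic decks therefore demonstrate
engine correctness and calibration identifiability — not fidelity of
any particular deck to real patients.

## Sensitivity analysis

* **One-way / tornado** (`one_way()`, `tornado()`): each scalar is
  scaled by low/high multipliers (default 0.5–2.0, i.e. halving to
  doubling) and the pairwise ICER recomputed; probabilities and
  utilities that leave [0, 1] are clamped with a warning. Swing is the
  absolute ICER difference.
* **Horizon sweep** (`horizon_sweep()`): truncated cohort runs at each
  follow-up horizon with the frontier rebuilt there.
* **PSA** (`psa()`): beta distributions for probabilities and
  utilities, gamma for costs, parameterized by method of moments
  around the deck value with a relative SD of 20% (the conventional
  default where a study reports no uncertainty inputs; per-parameter
  overrides via the `dist_spec` table). Within an iteration the same
  quantile is applied to the corresponding parameter of every strategy
  (common random numbers), which sharpens incremental comparisons.
  Acceptability curves split exact NMB ties equally; at each threshold
  the probabilities sum to 1. Published acceptability percentages
  depend on uncertainty distributions the source does not state, so
  the package checks direction only: AM is modal at low
  willingness-to-pay, PR at $50,000/QALY, RT at $100,000/QALY.

## Numerical choices and problem sizes

* Root-finder tolerance 1e-7 relative, so calibration errors are
  dominated by arithmetic, not the stopping rule; parameter-recovery
  tests assert 0.1%.
* Degenerate CEA inputs (equal cost and effect) are flagged as
  dominated/equivalent rather than producing undefined ICERs; a
  single-strategy report is degenerate but not an error.
* The test suite uses 20,000-patient microsimulations for the
  engine-agreement checks, 200–300 PSA iterations for curve-shape
  checks, and 10,000 quantile draws for distribution-moment checks;
  the acceptance script uses 2,000 PSA iterations. These sizes put
  Monte Carlo noise well inside the asserted bounds (3 SE) while
  keeping a full run around half a minute.
* All randomness flows from explicit integer seeds; no function draws
  from an unseeded stream, and engine/PSA functions restore the
  caller's RNG state.

## Known limitations

* Homogeneous cohort: no age-, grade- or PSA-level-specific hazards;
  results apply to the 50–69 trial-like population.
* Adverse-event onset is tied to the first treatment year regardless
  of salvage treatment later; patients converting from AM do not
  acquire the salvage modality's complication profile (its cost is
  carried by the salvage one-time cost).
* Patient-level cost SDs are reported but not calibrated: the
  published SDs imply a heavily skewed cost distribution (AM SD larger
  than its mean) that a two-point adverse-event cost model cannot and
  does not attempt to match.
* Brachytherapy, cryotherapy and newer radiotherapy modalities are out
  of scope, as in the source analysis.
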