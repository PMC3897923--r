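---
title: "A Markov cohort model of waiting for total knee arthroplasty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model of waiting for total knee arthroplasty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tkawait)
```

## The decision problem

A 60-year-old with end-stage knee osteoarthritis (OA) who has exhausted
non-operative care will eventually receive a total knee arthroplasty
(TKA).  The policy question is what a *waiting period* before that
surgery costs.  `tkawait` evaluates three strategies over the cohort's
remaining lifetime: immediate TKA, a delay at the untreated OA utility,
and a delay softened by a non-operative treatment bridge.  Outcomes are
discounted total cost and quality-adjusted life years (QALYs); strategies
are compared by incremental cost-effectiveness ratios (ICERs), dominance
on the cost-effectiveness frontier, and net benefits at a willingness to
pay (WTP) of $50,000/QALY.

## State space and transitions

The cohort engine (`cohort_model()`, `propagate()`, `accumulate()`) is a
generic discrete-time Markov cohort machine with a one-month cycle; the
strategy builder (`build_strategy()`) assembles the clinical model:

* **wait** — delayed strategies only; background mortality; exits to
  surgery after `wait_months` cycles (snapped to whole months, so the
  "3-week" lower end of the wait range maps to one cycle).
* **post-TKA month** — a one-cycle state entered at surgery.  The
  procedure cost and any one-time disutility are charged on the entering
  flow, and the 30-day excess mortality is combined with background
  mortality for that single cycle.
* **well TKA** — background mortality plus an implant-age-tiered monthly
  revision hazard (`revision_monthly_prob()`): zero in the implant's
  first year, then the annual tier value (years 0–9, 10–19, 20+)
  converted to monthly.  Because the whole cohort is operated in a single
  cycle, the primary implant's age is a deterministic function of the
  cycle index and needs no extra states.
* **revision pathways** — a revised patient passes through a one-cycle
  post-revision state (revision cost, −0.1 QALY recovery deduction,
  30-day revision mortality) into a *well revision* state.  Revision
  times vary across the cohort, so time-since-revision is tracked
  explicitly by a monthly tunnel (240 clock states, then a terminal
  "20+ years" state) so that revision-of-revision hazards follow their
  own tier table.  After a second revision no further revision is
  modelled, so the last well state needs no clock.
* **dead** — absorbing; forced at the age cap (110), where the life
  table's annual death probability is 1.

Competing monthly risks are ordered: background death is applied first,
and revision (or procedure) events occur among survivors, combined
multiplicatively (`combine_risks()`).  At the hazards involved the
ordering changes results by less than one part in $10^4$.

## Rewards, scenarios and discounting

Utilities are annual quality weights (OA 0.6, OA with bridge 0.7,
primary TKA 0.9, revision TKA 0.85); each cycle accrues one twelfth of
the annual rate, weighted by start-of-cycle occupancy.  No half-cycle
correction is applied by default — with monthly cycles the correction is
well under 0.5% — but `accumulate(..., half_cycle = TRUE)` exposes it for
sensitivity work.  One-time rewards (procedure costs, recovery
disutilities) are weighted by the transitioning mass and discounted at
the cycle in which that mass arrives, which makes an immediate surgery a
cycle-0 charge and a surgery after a w-month wait a charge at discount
$v^w$.  Discounting compounds monthly, $v = (1+r)^{-1/12}$ with $r =
0.03$/year, so twelve cycles equal one annual discount step.

Cost scenario **A** counts direct medical costs only: the primary and
revision episode costs ($26,865 and $35,542, each covering the first 90
days including rehabilitation) and, for the bridge strategy, the bridge's
direct cost ($2,500/year while waiting).  Scenario **B** adds the
indirect cost of end-stage OA ($10,369/year) during the wait and its
residual after surgery: TKA is assumed to eliminate a fraction
(`indirect_recovery_fraction`, base 0.80) of the indirect cost, leaving
$(1-0.8) \times \$10{,}369 \approx \$2{,}074$/year from the surgery month
onward (whether the first post-operative month is charged at the full or
the residual rate is not observable in published summaries; the residual
rate is used from the surgery month on).

Early post-operative complications are not modelled as explicit states;
the expected one-time deduction
`p_early_complication * dis_complication` ($0.01 \times -0.20$ QALY) is
charged at primary surgery when `include_complications = TRUE` (the
default), and the toggle removes it.  At base values the effect is
−0.002 QALY, far below reporting precision either way.

### The treatment bridge

Two representations of the bridge's benefit are supported.  By default
the waiting utility is the explicit `u_oa_bridge = 0.7`; when that field
is `NA` it is derived as closing a fraction
(`bridge_utility_improvement`, base 0.33) of the OA→TKA utility gap,
$0.6 + 0.33\,(0.9-0.6) \approx 0.7$ — the two parameterizations agree at
base values.  A second dial, `bridge_relief_months`, limits how long the
relief lasts within the wait: the waiting utility is `u_oa_bridge` for
that many months (fractional months interpolate the boundary cycle
linearly) and reverts to `u_oa` afterwards, while bridge *costs* continue
for the whole wait.  This supports the "how much relief must the bridge
deliver to be worth buying" threshold question, including the variant of
full relief for a quarter of the wait.

## Inputs

* **Parameters** — `parameter_set()` / `load_parameters()` (YAML; keys
  are exactly the field names, all dollars and annual rates documented in
  `?parameter_set`).  Validation enforces utilities in $[0,1]$,
  disutilities in $[-1,0]$, probabilities in $[0,1]$, non-decreasing
  revision tiers and non-negative costs/waits.
* **Life table** — CSV `age,qx`, contiguous integer ages
  (`read_life_table()`).  Lookup floors the cohort's age, so monthly
  mortality is piecewise constant within a year of age; interpolation
  would change lifetime totals by less than reporting precision.
* **Synthetic life table** — the bundled fixture is *generated*, not
  copied: a two-parameter Gompertz hazard
  $q(x) = 1 - \exp(-a e^{bx})$ with $a = 4.1521\times 10^{-5}$,
  $b = 0.09$, calibrated so life expectancy at 60 is ≈ 22.6 years, in
  line with a US 2009 all-sex period table.  Adult mortality (the only
  region a 60-year-old cohort ever sees) is realistic; childhood
  mortality is not, and no attempt is made to match any specific national
  table age-by-age.  Tests passing against this table therefore
  demonstrate correct model mechanics and realistic adult survival, not
  agreement with any particular country-year life table.
* **Procedure volumes** — population projections require a user-supplied
  `year,volume` CSV; the bundled `volumes_synthetic.csv` is an
  illustrative synthetic ramp for tests, not a demand forecast.

`sample_parameter_sets()` draws parameter sets uniformly and
independently over the deterministic sensitivity ranges (a least-
assumption choice — the analysis itself is deterministic, so no
distributional claim is made); independently drawn revision tiers are
monotonized with a running maximum to restore the tier invariant.  A
single integer seed makes draws reproducible.

## Analysis surface

* `build_cea_table()` sorts strategies by effectiveness, removes strongly
  dominated ones, flags extended dominance (implemented although the
  three base-case strategies never trigger it), and walks the frontier
  accepting steps with ICER ≤ WTP; a tie at exactly the WTP resolves to
  the more effective strategy, and the preferred strategy provably
  maximizes net monetary benefit (property-tested against brute force).
* `threshold_parameter()` bisects any named parameter for a predicate
  flip; tolerances default to $0.01 on dollar quantities and 0.001 on
  fractions.  Bisection (rather than derivative methods) is used because
  outcomes are piecewise-smooth and cheap to evaluate, and a bracket
  without a sign change is reported as an error, never guessed.  The
  canned switch points: the monthly indirect cost above which immediate
  TKA is cheaper than delaying (societal scenario), the monthly bridge
  cost below which the bridged delay is cheaper than immediate TKA, the
  indirect-recovery fraction making immediate TKA cheaper, and the months
  of bridge relief making the bridge worth buying relative to waiting
  untreated.  For the indirect-cost threshold the binding comparator is
  the *unbridged* delay: against the bridged delay immediate TKA is
  already cheaper at zero indirect cost (the bridge's direct cost exceeds
  the saving from postponing and discounting the surgery), so no switch
  point exists on that comparison.
* `wait_time_sweep()` evaluates waits from three weeks to five years;
  `sweep_parameters()` re-runs the model over 1–3 parameter grids;
  `per_patient_incremental()` / `population_projection()` scale the
  per-patient cost of delay by projected procedure volumes, with no
  discounting across calendar years (each annual cohort is valued at its
  own start).

## Numerical conventions and problem sizes

Transition matrices are validated row-stochastic to $10^{-12}$ with an
absorbing death row; occupancy mass is conserved to $10^{-9}$ over a full
run.  Propagation stops at full absorption (living mass below
$10^{-12}$) or the age cap — 612 monthly cycles for the base-case
60-year-old cohort — and extending the horizon beyond absorption changes
totals by less than $10^{-12}$.  The engine is verified against
closed-form geometric-series oracles on constant-hazard models to
$10^{-9}$.  Matrices are cached within a run (they change only at yearly
age boundaries, the surgery cycle and implant-age tier boundaries), so a
full strategy run is a fraction of a second; test and acceptance runs use
the full 612-cycle horizon throughout, with sweeps run on a shortened
(age-75-cap) configuration where only qualitative structure is asserted.

## Known limitations

* The base case reproduces the *qualitative* published decision structure
  exactly (cheapest/least-effective ordering in the direct-cost scenario,
  immediate TKA preferred at $50,000/QALY, strong dominance of both
  delays in the societal scenario) and matches published *incremental*
  quantities closely, but its *absolute* discounted levels run higher
  than the printed reference averages.  Those printed averages cannot be
  produced from the printed inputs by any cohort model of this structure
  — the reference direct-cost average for immediate TKA is lower than
  the procedure cost it includes — so the package reports its own
  faithfully computed levels rather than calibrating toward inconsistent
  targets; the acceptance tests state both values side by side.
* Contralateral knee disease, bilateral TKA, infection-specific revision
  pathways, waiting-related excess mortality and a definitive
  non-operative pathway are out of scope; the bridge never averts the
  eventual TKA.
* Probabilistic sensitivity analysis (distributions, acceptability
  curves) is not implemented; sweeps and thresholds are deterministic.
* Costs are modelled as stated episode prices; no claims-data estimation
  or inflation adjustment is performed.
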