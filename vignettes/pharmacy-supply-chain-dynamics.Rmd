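---
title: "Modelling the sustainable drug supply chain of an inpatient pharmacy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the sustainable drug supply chain of an inpatient pharmacy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hospital inpatient pharmacies sit at the end of a drug supply chain whose
sustainability is threatened from two sides: slow-moving ("low-consumption")
medicines expire on the shelf and must be disposed at a cost, while
fast-moving ("high-consumption") medicines are exposed to ordering delays and
seasonal demand. Staffing — the competence of the workforce, the speed with
which the pharmacy responds to requests, and whether pharmacists take part in
the prescribing team — modulates both: a responsive, well-staffed pharmacy
sells more near-expiry stock before it is lost, keeps its shelves stocked,
and wastes less.

`pharmsd` models this system with the system dynamics method: a causal loop
diagram captures the feedback structure among the sustainability challenges,
a stock-and-flow model turns that structure into equations integrated over a
24-month horizon, validation tests probe the structure and its limiting
behaviour, and policy scenarios apply step changes to staffing levers and
compare the resulting trajectories against a baseline run.

## Causal loop diagram

The diagram is a signed digraph over seventeen challenges, each typed as a
*cause* or an *effect* by an upstream expert-consensus (fuzzy Delphi)
elicitation that this package does not re-run. A closed directed cycle is a
feedback loop; a loop with an even number of negative links is *reinforcing*
(it amplifies change), with an odd number *balancing* (self-correcting).

The original study names the challenges and narrates two loops but does not
print a machine-readable edge list or edge signs. The packaged graph
(`inst/extdata/causal_*_synthetic.csv`) is therefore a documented **synthetic
reconstruction**, engineered to satisfy the reported structure: 17 nodes, 10
cause-type and 7 effect-type, exactly eight simple loops. The two narrated
loops are realized directly:

* **R1** (reinforcing): lack of a certified financial manager → inadequate
  liquidity management → insufficient cost-profitability analysis → and back
  to the decision not to employ a financial manager. All links positive.
* **B1** (balancing): poor emergency responsiveness → incorrect procurement
  prioritization → last-minute procurement of urgently needed drugs. A
  narrated chain in problem terms reads as same-direction links throughout,
  which would make the loop reinforcing; to honour the balancing label the
  reconstruction closes it through drug shortages with one negative link —
  last-minute emergency purchases *relieve* the immediate shortage — so the
  loop is self-limiting: shortages degrade responsiveness, degraded
  responsiveness distorts prioritization, and emergency purchasing partially
  relieves the shortage. This sign choice is a modelling decision of this
  package.

```{r}
library(pharmsd)
report <- structure_counts(reference_causal_graph(),
                           reference_loop_annotations())
report
```

Loop enumeration is an ordered-start depth-first search (each cycle is rooted
at its lexicographically smallest node, so every simple cycle is found exactly
once, up to rotation; a cycle and its reverse are distinct unless both edge
directions exist). The test suite checks it against an exhaustive brute-force
permutation oracle.

## The stock-and-flow model

### Integrator

The engine integrates with fixed-step forward Euler (`dt = 0.25` month by
default, configurable) — the default method of the Vensim PLE software this
model family is usually built in. The original study does not state its
integration settings, so exact numeric agreement with those runs is not
attainable and not targeted. All
auxiliaries and flows are evaluated synchronously from the time-`t` state,
then all stocks advance together — declaration order never affects results.
Being first-order, Euler's global relative error on a decay process
`dS/dt = -lambda S` is `exp(T lambda^2 dt / 2) - 1`; the tests assert this
law directly (the dt = 1/64 decay run lands inside a bracket around the
prediction, and halving `dt` halves the error).

Stocks that hold physical material (inventories, the expiring-stock pool, the
resident head count) are flagged non-negative: if a step would overdraw one,
its outflows are scaled down proportionally so the stock floors at zero, and
the scaled flow values are what downstream stocks receive — material is
conserved, as `check_conservation()` verifies on every run. The money stock
(pharmacy profit) is deliberately *not* flagged and may go negative.
Auxiliaries derived from a flow elsewhere in the model (for example the
disposal *cost* computed from the disposal rate) are evaluated before the
limiting pass; at the reference calibration no stock ever reaches its floor,
so the distinction is moot there.

### Structure

Six reported stocks: `pharmacy_profit` (MU), `number_of_residents` (persons),
`total_expiring_medicines` (packs), `total_disposed_medicines` (cumulative
packs), `inventory_high_consumption` (packs) and `cumulative_disposal_cost`
(MU); plus three internal stocks: the staff-accuracy smooth, the launch-phase
sales drive, and the in-transit ordering pipeline.

The slow-mover chain: expiring stock is fed by a base arrival rate plus a
resident over-prescription term proportional to the number of residents
(residents enter at a constant intake rate and graduate after an average
residency duration). Stock leaves by three routes — sales before expiry,
transfer to other pharmacies (`transfer_rate_coeff` per month; the
"exchange between pharmacies" is interpreted as physical drug transfer, at
cost, with no profit contribution), and disposal (`expiry_fraction` per
month, reduced by the share of stock committed to transfers). Because
disposal is proportional to the stock, growing expiring stock yields
accelerating cumulative waste and waste cost.

The fast-mover chain: demand is sinusoidal,
`demand_high_base * (1 + amplitude * sin(2 pi t / period))`; orders are a
share of the monthly purchase, scaled by a saturating service factor and the
seasonal demand index, and arrive through a first-order material delay of
`order_delay` months. Sales deplete inventory through a saturating
availability term. This is the robust route to the described sinusoidal
buying/selling pattern; a purely endogenous delay-loop oscillation would be
admissible but is much harder to guarantee across parameter ranges.

Money: profit inflows are the margins on both sales channels (the
high-consumption pack price is an internal calibration ratio of
`avg_price_low`, as the parameter set carries no second price field);
outflows are disposal cost, wages (`avg_salary * staff_count`), overhead, and
a transient error cost described below.

### Reference functional forms

The original study publishes the influence structure and qualitative behaviour of
every variable but **no equations**. The functional forms are therefore owned
by this package:

* `response_speed = response_speed_base * workforce_competence^a *
  (1 + b * pharmacists_in_team)` with `a = 0.5` (diminishing returns to
  competence) and `b = 0.25` per pharmacist.
* Sales of low-consumption medicine before expiration: proportional to
  `response_speed`, a unit-margin incentive saturating in
  `profit_margin_low * avg_price_low`, a launch drive (below), a saturating
  availability in the expiring stock, and the share of stock not committed
  to transfers.
* **Accuracy smooth**: a first-order smooth tracks the *response pace*
  (`response_speed_base`) with adjustment time `accuracy_adjust_time`; while
  actual pace exceeds the adapted level, an error cost proportional to the
  relative gap drains profit. The smooth deliberately tracks the pace
  constant rather than the full service level: the reported behaviour shows
  the adjustment dip only for the response-speed lever (scenario S2's early
  months below baseline), while the competence lever produces a steady gain
  from the start (S1) — an adaptation cost tied to overall service would
  make those two observations mutually inconsistent, since gains and costs
  would then scale with the same factor.
* **Launch drive**: the initial sales surge ("notable surge in the first two
  months") is modelled as a clearance drive — a smooth starting at 2.0 and
  decaying to its long-run level 1 with a 0.8-month time constant,
  representing the start-of-programme push to sell accumulated near-expiry
  stock. The original account narrates the surge without a mechanism; this is the
  package's interpretation.

### Scenario mechanics

Scenario overrides are multiplicative step changes applied at `t = 0`
(timing unstated in the original study; a step at the start is the simplest faithful
choice). All stock initial values — including the internal adaptation stocks
— are taken from the *baseline* parameter set (`init_params` argument of
`build_pharmacy_model()`), so a scenario meets a system still adapted to the
pre-intervention operating point; this is what produces S2's adjustment dip.
The fourth scenario describes an *increase* in pharmacist involvement while
the third *halves* it, so S4 uses the mirrored multiplier (x2) on
`pharmacists_in_team` together with doubled competence and response speed.

## Parameters and calibration

All 28 parameters carry abstract units (MU, packs, persons, months) — no real
prices or wages are claimed. The packaged reference set
(`inst/extdata/reference_parameters_synthetic.json`) is a **synthetic
calibration**: the survey values behind the original model (16 inpatient
pharmacies; one passage of the original study says 17 — the cohort default here is
16) were never published. Values were chosen by stock-flow balance reasoning
(e.g. the initial expiring stock sits at the operating point where inflow
balances outflow under the early launch-drive sales level, which is what
makes the expiring stock initially flat) and refined against the pattern
classifier, then frozen. The calibration must reproduce, at `dt = 0.25` over
24 months:

* cumulative disposed medicines: increasing and accelerating (second
  12-month delta exceeds the first);
* expiring stock: flat over the first two months (within 5% of the total
  24-month change), rising thereafter;
* cumulative disposal cost: increasing and accelerating;
* cumulative low-consumption sales: initial two-month surge, growth
  afterwards;
* profit: increasing and decelerating (first 12-month delta larger);
* high-consumption buying and selling: oscillatory (at least two detrended
  local maxima and minima each on the monthly grid);

and the scenario responses: S1 profit strictly above baseline at all times;
S2 below baseline initially with a single crossing within six months and
lower expiring stock at the horizon; S3 at or below baseline throughout; S4
dominating baseline with the best 24-month profit.

## Synthetic cohorts

`sample_cohort()` emulates the multi-pharmacy survey: each member is drawn
from documented ranges (`inst/extdata/parameter_ranges_synthetic.json`,
roughly ±25% around the reference; uniform for fractions, indices and
counts, log-uniform for strictly positive scale parameters). Sub-seeds come
from a splitmix-style 32-bit hash of `(master seed, index)`, so cohorts
regenerate exactly and member `i` does not depend on cohort size. Fields are
sampled independently — the generator emulates dispersion across pharmacies,
not the correlation structure real bookkeeping would show, so ensemble
results speak to robustness of the model's qualitative behaviour, not to any
real cohort. The committed robustness property is that the
increasing-and-accelerating waste pattern holds in at least 80% of a default
cohort; the trajectory-shape patterns tied to the initial operating point
(e.g. the flat start of the expiring stock) are *expected* to degrade away
from the calibrated balance point, and do.

## Validation tests

* **Structure verification**: the dependency set of every flow and auxiliary
  (extracted automatically from its equation) must equal the shipped
  influence table; missing and extra drivers are both reported.
* **Parameter verification**: every field inside its declared valid range
  (fractions in [0, 1]; rates, prices, durations positive; initial stocks
  non-negative); unknown fields are errors.
* **Boundary adequacy**: zero limits of the resident pipeline. Rates go to
  exactly 0; "infinite" residency duration is 10^6 months (graduation
  effectively zero while the division stays well posed). Zero intake gives
  monotone exponential decay of residents matching `R0 exp(-t/T)` within the
  Euler error; zero intake *and* zero graduation hold residents constant; no
  residents at all removes the over-prescription component of the expiring
  inflow and keeps the expiring stock strictly below baseline at the horizon.

The trend classifier resamples every series to monthly points (nearest grid
point) before labelling, so classifications are independent of the
integration step; its operational definitions (tolerances, the two-month
surge and flatness windows, the 5% flatness threshold) are fixed constants
of the package. "Flat then increasing" for the expiring stock is asserted as
the flatness label plus monotone growth from month 2 onward, allowing the
sub-5% settling movement within the first two months that a global
monotonicity label would forbid.

## Problem sizes and numerical choices

The default run is 96 Euler steps (24 months at `dt = 0.25`); the acceptance
workflow simulates the reference run, five scenario runs, three boundary
runs and a 16-member cohort, all in a few seconds. The convergence tests use
`dt` down to 1/512 month on a one-stock model. Ties in dominance fractions
(scenario exactly equal to baseline) count against dominance; crossing times
are located by linear interpolation between grid points.

## Known limitations

* No sensitivity analysis (explicitly out of scope, matching the original study);
  the synthetic-cohort ensemble is a robustness check, not a calibrated
  uncertainty analysis.
* Single pharmacy, single aggregated drug per consumption class — no SKU
  granularity, no multi-pharmacy network (transfers leave the system).
* Equations and the calibration are reference reconstructions; conclusions
  about any real pharmacy would require re-estimating parameters from that
  pharmacy's records.
* Units are declared strings; no dimensional algebra is performed.
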