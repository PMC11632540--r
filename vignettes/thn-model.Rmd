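---
title: "Modelling take-home naloxone distribution with jail circulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling take-home naloxone distribution with jail circulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`thnsim` simulates opioid-related overdose events and deaths, day by day,
in a synthetic urban population whose criminal-legal-system-involved (CLI)
members circulate through a county jail, in order to evaluate take-home
naloxone (THN) distribution policies.  This vignette records the model, its
assumptions, the tunable parameters, and the numerical and design choices
made where more than one reasonable option existed.

## The population and the jail

`build_population()` creates three overlapping groups: injection opioid
users (IOU, default 24,000), non-injection opioid users (NIOU, 66,000), and
a CLI pool (50,000) from which jail bookings are drawn.  The CLI pool
contains a configurable fraction of each user type (defaults 3.5% IOU,
10.5% NIOU — the midpoints of the swept ranges); the rest of the pool does
not use opioids and carries zero overdose hazard.  Because bookings sample
uniformly from the CLI pool, the expected in-custody composition equals
those fractions, which is how the inmate-composition figures the model is
built around are imposed.

Two demographic marginals are deliberately exposed placeholders:
`sex_female_frac = 0.25` and `age_dist = (0.10, 0.15, 0.75)` over ages
18–24 / 25–29 / ≥30.  The data that would pin them down are not public at
the resolution the model needs, so they are configuration keys, not
constants.  They matter: the age and sex relative risks multiply into every
hazard, so the *absolute* baseline death toll — and with it every
cost-per-death and NNT figure — scales with this choice, while percentage
outcomes (deaths averted relative to baseline) are largely insensitive to
it.  Users calibrating to a specific jurisdiction should set these (and
`p0_daily_od`) against local surveillance counts.

The jail is a queue: bookings arrive Poisson (`booking_rate = 132`/day),
each booked person draws a stay from a log-normal distribution fitted to
the published median (12 d) and mean (54.1 d):
`meanlog = log(12)`, `sdlog = sqrt(2 log(54.1/12)) ≈ 1.7355`.  The
log-normal is the minimal two-parameter family reproducing both statistics
with the observed heavy right tail; stays are rounded up to whole days.
Note a deliberate, documented tension: Little's law gives a steady-state
census of `132 × 54.1 ≈ 7141`, while the census the model targets at
start-up is the reported ~6000.  We expose `census_target` for the
warm-up seed and let the census drift toward its own equilibrium rather
than silently resolving the discrepancy; with a 90-day warm-up and a
365-day horizon, the drift over the simulated year is modest.

`initialize_steady_state()` seeds custody at `census_target` with
length-biased total stays (log-normal with location `meanlog + sdlog²`) and
uniform elapsed fractions.  Starting from an empty jail instead would leave
the census far below steady state for the entire warm-up, because 90 days
is short relative to the 54-day mean stay.

## Overdose hazard and the bystander tree

Each alive, out-of-custody opioid user overdoses on a given day with
probability `min(1, p0 × RR)`, where `RR` multiplies relative risks for
sex, injection use, age group and the post-release window.  Windows are
0-based and half-open — days [0, 14) since release map to weeks 0–2,
[14, 28) to weeks 3–4, ≥28 to week ≥5 — and the ≥5-week multiplier persists
for life (the reference category is "never incarcerated").  The clamp at 1
only binds in pathological corners of the sensitivity hypercube.  Hazards
are zero in custody; at most one overdose per person per day (daily tick
granularity); fatal and nonfatal overdoses share all multipliers, since the
published risk estimates cannot be decoupled.

A witnessed overdose resolves through a probability tree
(`resolve_overdose()`, with `analytic_death_probability()` as its
closed-form oracle): bystander present with probability `p_bystander`;
if present, naloxone administered with probability `p_administer` *when a
kit is available at the scene*, and EMS called independently with
probability `p_ems`.  Fatality is `f_fatal` times a survival multiplier:
`1 - eff_naloxone` (default 0.95) if naloxone was administered, else
`1 - eff_ems` (default 0.50) if EMS was called, else 1.  Three choices
deserve comment:

* **No stacking.**  Naloxone administration dominates; the EMS effect
  applies only when no naloxone is given.  This avoids double-counting
  reversal.
* **`eff_ems` is a modelling assumption**, not a published estimate; the
  main sources give no EMS-only effect size.  It is a visible
  configuration key with a deliberately moderate default (0.50).
* **Independence.**  Whether the administer and EMS decisions are drawn
  sequentially or independently within the tree is not documented in the
  sources; we draw them independently.  `eff_naloxone` defaults to the
  proper-and-prompt-use figure (0.95, configurable down to 0.80);
  imperfect use is already captured by `p_administer`.

"Willingness" of the bystander carries no separate probability: it is
folded into `p_administer` and `p_ems`, which is exactly what the published
parameter table exposes.

## THN channels and the kit ledger

Community distribution happens once, at horizon start: every alive opioid
user receives a kit with probability `cov_community` (a one-time assignment;
no ongoing community inflow is modelled).  At each release during the
horizon, an opioid-using person receives a kit with probability `cov_jail`
and acquires a kit-holding peer (flag, not a network graph) with
probability `cov_network`.  A person holds at most one own kit and one peer
flag; re-receipt is idempotent and not double-counted — the ledger counts
kits, not offers.  Kits survive re-incarceration, and a used kit is
replaced immediately (`used == replacements` at all times).  Total kits =
community + jail + network + replacements; cost and NNT metrics use the
replacement-inclusive total, and `total_kits(ledger, include_replacements
= FALSE)` gives the other convention.

## Scheduling, randomness, and common random numbers

Each day runs in a fixed order: (day 0: community distribution) → bookings
→ releases → jail/network distribution → overdose draws → event resolution
→ tallies → post-release clocks.  Event resolution order within a day is
irrelevant by construction — every decision has its own independent random
source — so no within-day shuffling is needed.

All within-loop randomness is *counter-based*: each decision consumes a
uniform computed as a 64-bit hash (two splitmix64 finalizer rounds) of
`(seed, person id, day, purpose)`.  Booking counts come from the Poisson
inverse CDF of a day-keyed uniform; without-replacement booking selection
uses attempt-keyed rejection sampling; stays come from the log-normal
quantile of a person/day-keyed uniform.  The payoff is exact common random
numbers: two runs that share a seed but differ in coverage agree on every
booking, stay, overdose occurrence and bystander decision that the
intervention does not causally touch.  Paired deaths-averted estimates are
then nearly noise-free (the baseline compared against itself averts exactly
zero), and responses are pathwise monotone: raising any coverage, or
`p_bystander`, can only turn fatal events non-fatal along a fixed
trajectory.  A conventional sequential stream loses this coupling as soon
as the first differential death shifts the draw sequence, which at desk
scale buries the small-coverage scenarios (~0.3% averted) in Monte Carlo
noise.

The population build and the steady-state jail seeding use R's ordinary
seeded generator (they are identical across compared scenarios anyway).
Sweep cells derive seeds from `(base_seed, draw, replicate)` via a
documented multiplicative mixing hash (`derive_seed()`), never arithmetic
offsets; scenarios deliberately do not enter the hash.  The compiled engine
and the pure-R engine (`engine = "r"`, built from the exported per-step
operations) consume identical uniforms and are bit-identical for any seed —
the test suite asserts this, which is the package's strongest guard against
engine bugs.

## Outcome metrics

Per draw, with the same-seed baseline: percent deaths averted (overall, and
restricted to persons with **at least one jail release during the
horizon**), NNT = kits / deaths averted, and cost per death averted =
$76 × NNT (identically, per draw).  Scenario summaries report medians and
IQRs (type-7 linear-interpolation quantiles, the method being otherwise
unspecified) across draws of replicate-averaged counts; undefined values
(zero baseline deaths, zero averted) are excluded and counted.  Formatted
reports round costs to the nearest $100 and NNT to one decimal, matching
the conventional presentation.

The released-subgroup definition has a consequence worth knowing: a person
who dies before ever being released never enters the subgroup, so under
100% jail-release coverage nearly all subgroup deaths occur in covered
person-time and the subgroup percentage averted is correspondingly high.
Definitions that also count persons released before the simulated year
would dilute this figure.

## Sensitivity analysis

`sample_parameter_draws()` samples the 14 swept parameters (hazard scale,
fatality, seven relative risks, three bystander probabilities, two inmate
composition fractions) by Sobol sequence (own implementation, Joe–Kuo
direction numbers, ≤16 dimensions), Latin hypercube, or uniform sampling —
the sources do not say which design generated their published medians, so
the method is an argument, and the defaults here use uniform draws.
`sobol_screening()` estimates first- and total-order indices with the
Jansen estimators over a Saltelli design (two seeded Latin hypercubes for
A and B); the same replicate seeds are reused at every design point, so a
collapsed parameter range yields a total-order index of exactly zero, and
stochastic noise largely cancels from the differences.  The screening
outcome for ranking parameters is the *percentage* of deaths averted among
released persons: count outcomes mix in the baseline-scale parameters
(`p0_daily_od`, relative risks), which is a different question.  Replicates
whose baseline subgroup records no deaths contribute zero averted percent
at their design point rather than a missing value.

## Problem sizes and what the tests establish

The bundled reproduction sweeps use 64 uniform draws over the published
ranges, the full 27-scenario grid, 3 CRN replicates per cell, and
population scale 0.1 (tests) or 0.2 (`scripts/acceptance.R`); screening
uses a Saltelli design with `n_base = 128` at scale 0.05.  Scale multiplies
all population counts, the booking rate and the census target jointly, and
summaries re-express kit counts per unscaled population.  These sizes make
the percentage outcomes and structural kit counts stable to well within the
published interquartile ranges; absolute-count noise shrinks with scale.

The synthetic conditions emulate the published setting's structure — subgroup
sizes, jail throughput, hazard ranges — not any particular surveillance
dataset.  Passing tests therefore establish internal correctness
(oracle equivalence, conservation laws, determinism, monotonicity) and
reproduction of the published *relative* outcomes under comparable
conditions; they do not validate the placeholder demographics, and
absolute dollar-per-death figures inherit that uncertainty directly, as
noted above.

## Limitations

No MOUD treatment cascade; no multi-dose naloxone or EMS response-time
variance; no explicit social-network graph (peer kits are a probability);
no recidivism-rate structure beyond uniform re-booking eligibility; no
race/ethnicity stratification; costs are undiscounted direct kit costs over
a one-year horizon, not a cohort cost-utility analysis.  In-custody
overdose hazard is zero by assumption.
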