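---
title: "Model structure, calibration and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, calibration and verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hivcea)
```

This vignette documents the model's assumptions, the numerical conventions
chosen where the published description is silent, and exactly what the test
suite does and does not establish.

## The disease and decision problem

Antiretroviral-naive HIV-infected adults start first-line therapy with one
of three strategies: LPV/r, ATV+r as observed in routine care ("ATV+r 1"),
or a trial-adjusted ATV+r variant ("ATV+r 2"). Disease status is
discretised into eight states on a CD4 × viral-load grid; odd-indexed
states are virologically suppressed (< 50 copies/mL), even-indexed states
detectable. The model advances in 6-month cycles because that is the
clinical monitoring interval; each cycle a patient faces background
mortality, a state transition, and independent draws for AIDS, coronary
heart disease (CHD), opportunistic infection (OI), chronic kidney disease
(CKD) and the arm's primary adverse event (AE). An AE, or ending two
consecutive semesters with detectable viral load, moves the patient
irreversibly to an aggregate second line. Costs and utilities accrue per
cycle and are discounted at 3% per year; the comparison metric is cost per
QALY and the incremental cost-effectiveness ratio at a willingness to pay
of €25,000/QALY.

## Transition-matrix calibration

Only the self-transition probabilities of the four 8×8 matrices (three
first-line arms plus the shared second line) are published. Two published
facts make a partial reconstruction exact rather than guessed:

1. ATV+r 2 is *defined* as LPV/r with every transition into a
   detectable-VL state 19% less likely.
2. All eight ATV+r 2 diagonals exceed the LPV/r diagonals.

If the removed mass is credited to the diagonal (the only reading
consistent with fact 2, including for rows that are already detectable),
then for every state
$d_{\mathrm{ATV2}} = d_{\mathrm{LPV}} + 0.19\,u$, where $u$ is the LPV/r
off-diagonal mass into detectable states. Hence
$u = (d_{\mathrm{ATV2}} - d_{\mathrm{LPV}})/0.19$ is identified per state
(`infer_upward_mass()`), and applying the reduction operator to the
completed LPV/r matrix reproduces the printed ATV+r 2 diagonals to all
printed digits *by construction* — which the tests verify by independent
enumeration of row mass rather than by re-running the constructor.

What is *not* identified is how $u$ and the remaining mass
$1 - d - u$ spread over individual destination states. The default
"rank-proportional" completion scheme weights destinations by
$1/(1 + |\Delta\text{CD4-stratum}|)$ within the detectable and suppressed
pools separately — an adjacency assumption: large CD4 jumps in six months
are rarer than small ones. For ATV+r 1 and the second line, where no
calibration constraint exists, each row assigns the same *proportion* of
its off-diagonal mass to detectable states as the corresponding calibrated
LPV/r row. Both choices are registered, pluggable schemes
(`completion_scheme()`), so their influence can be probed; a uniform scheme
ships as the alternative. Every constructed matrix is validated
row-stochastic to 1e-12.

## Event processes

* **AIDS** risk is state-specific (0.09% to 94.35% per semester, ordered by
  disease severity). The published account says AIDS "may lead to death"
  without giving a probability; the case fatality is therefore an explicit
  configuration parameter, `risks$aids_case_fatality`, defaulting to 0
  rather than to an invented number.
* **CHD** risk comes from the (prior diabetes, prior CHD) stratum
  (0.17/0.82/3.75/4.94% per semester); an event makes the history
  permanent, moving the patient into a prior-CHD stratum and onto the CHD
  utility column. On first line the risk is multiplied by
  $1 - 0.14\,|\Delta \mathrm{TC{:}HDL}|$ (−0.17 for LPV/r, −0.40 for
  ATV+r); the cholesterol effect is null on second line. 35.4% of CHD
  events are fatal.
* **OI** risk is constant (1.76% per semester), affecting only cost and
  utility, never mortality — so the OI rate per 1000 patient-years,
  $\approx 0.0176 \times 2 \times 1000$, is invariant to the mortality
  schedule. This is the one event rate that is exactly anchored to a
  printed outcome, and it is an acceptance check.
* **CKD** risk ramps geometrically from 0.12% at cycle 1 to 2.9% (LPV/r)
  or 23.3% (ATV+r) at cycle 40 and is constant thereafter; geometric
  (log-linear) interpolation was chosen because the endpoints span a
  24-fold and 194-fold range, which a linear ramp would front-load
  implausibly. On switching, the risk freezes at its last first-line
  value. CKD affects neither mortality nor effectiveness.
* **AEs** (diarrhoea 1.76%/semester under LPV/r, hyperbilirubinemia
  1.47%/semester under ATV+r) occur on first line only and trigger the
  switch.

All events are recurrent — drawn independently every cycle — which is what
allows event rates far above cumulative-incidence levels, and "patients
with ≥ 1 event" to be reported separately.

## Cycle order and accrual conventions

The published description fixes no within-cycle order; one auditable
convention is used throughout (and mirrored exactly by the verification
oracle): background death → transition → AIDS → CHD → OI → CKD → AE →
switching → accrual. Consequences worth knowing:

* A death of any cause suppresses that cycle's cost, QALY and survival
  accrual; events drawn before an event death still count in event rates.
* Switching takes effect before accrual: the switch cycle already accrues
  second-line utility and counts toward second-line time.
* Discounting uses the cycle midpoint, $t = (c - 0.5) \times 0.5$ years,
  with factor $(1.03)^{-t}$; there is no half-cycle correction on
  transitions.
* The entry state does not count toward the two-consecutive-detectable
  rule (the counter starts at 0), so the earliest possible switch by that
  rule is at the end of cycle 2.
* The cycle utility weight is the *minimum* of all applicable columns
  (state baseline or flat second-line weight 0.7810; the CHD column for
  patients with CHD history; event columns for events fired).
  A multiplicative combination (`utilities$combine = "multiplicative"`) is
  available; minimum is the default because the event columns are already
  state-specific absolute weights, not decrements.
* State costs are annual and accrue at half value per semester. The same
  per-arm state-cost column is used on both lines (no separate second-line
  cost table is published). "Per capita mean annual cost" is mean
  discounted lifetime cost divided by mean undiscounted survival — the only
  definition consistent with the published outcome table's arithmetic.
  (That table's "Total cost" row is self-consistent only if read per 1,000
  patients; the package reports per-patient lifetime cost instead.)

## Synthetic mortality and cohorts

The original analysis used a national 2010 life table with
mortality-rate-ratios (MRR) from a European HIV cohort; neither input is
published. The package ships a Gompertz–Makeham stand-in,
$h(a) = \alpha + \beta e^{\gamma a}$, with sex-specific defaults
(male $\alpha = 2\times10^{-4}, \beta = 2.7\times10^{-5}, \gamma = 0.093$;
female $\alpha = 10^{-4}, \beta = 1.3\times10^{-5}, \gamma = 0.099$)
approximating a modern Western European population, closed at age 110, and
a single configurable MRR defaulting to 3.0 — a typical all-cause excess
for treated HIV cohorts, flagged as an assumption. Any real table can be
supplied as a CSV of (age, sex, qx). Annual probabilities convert to
semestral ones under constant within-year hazard, $1 - (1-q)^{1/2}$, with
the MRR applied on the hazard scale.

Baseline cohorts draw age from a normal(39.2, 9.5) truncated at 18 (adults
only; inverse-CDF sampling, which shifts the mean to 39.52), sex (75.9%
male), prior diabetes (3.8%) and prior CHD (1.2%) independently. The
initial health-state distribution is not published; the default places all
mass on detectable states — enrolment required viral load ≥ 5000
copies/mL — split 45/35/15/5% over states 2/4/6/8, a CD4 mix typical of
treatment initiation at the study period. Both are configuration knobs.

## Verification design

The stochastic engine is checked against a deterministic cohort recursion
(`occupancy_recursion()`) that propagates exact occupancy over
(8 first-line states, 8 second-line states, death). The
two-consecutive-detectable rule is Markov in this space because a
first-line patient's detectable counter equals 1 exactly when the current
state is detectable (a count of 2 would already have switched), with a
special case at entry. The oracle handles OI and AIDS (zero case fatality)
exactly, since those draws are independent of history; it deliberately
omits CHD (history-dependent) and CKD (switch-time-dependent frozen risk),
and equivalence tests disable exactly those. Agreement is required within
3 Monte-Carlo standard errors at 100,000 patients for occupancy (cycles 1,
10, 40) and for mean survival, QALY and cost.

Further property tests: QALY ≡ survival under unit utilities and zero
discount; discounted ≤ undiscounted QALY ≤ survival; mean survival against
the life-table recursion (and that recursion against an independent
survival-only Monte-Carlo); a two-state chain against its closed-form
geometric convergence; CKD ramp endpoints hit exactly with monotone
interpolation and post-switch freezing; OI rates invariant to swapping
life tables; byte-identical reruns under a fixed seed.

## Probabilistic sensitivity analysis

The PSA redraws: CHD case fatality Uniform(0.254, 0.454); diarrhoea
Beta(8, 448); hyperbilirubinemia Beta(3, 189); OI Beta(11, 637); CKD ramps
±10%; TC:HDL effects Normal(−0.17, 1.56) and Normal(−0.40, 2.82), truncated
at 0 by inverse-CDF (a positive "effect" would invert the risk-reduction
formula); the ATV+r 2 reduction Uniform(0.09, 0.29) in magnitude; state
utilities ±5%; CHD and every event utility column ±10% (the published
parameter list names both a "HS QALY weight ±5%" and a "health state QALY
weight ±10%" — an ambiguity resolved here as baseline-vs-event-column
knobs); state costs ±3%; CHD/CKD/OI costs ±20/5/10%. Parameters shared
between the ATV+r arms move with a single draw; sampled probabilities are
clipped to [0, 1]; the flat second-line utility is re-tied to the sampled
state-7 weight; invalid draws are rejected with bounded retries.

Each outer draw simulates both arms with common random numbers — the same
cohort and the same event uniforms — so inner-loop noise largely cancels
from the incremental estimates (a property the tests assert by comparing
delta variances against independent streams). The full design is 200 outer
draws × 5,000 patients; both are arguments, and the test suite exercises
the machinery at desk scale (hundreds of patients), which is sufficient
because every PSA check is a property, not a level.

## What the tests do and do not show

Anchored to printed values: the calibrated ATV+r 2 diagonals (exact), the
OI event rate (35.4/1000 patient-years ± Monte-Carlo noise), cohort
demographics, the CKD ramp endpoints, and all base-case parameter values.
Not anchored: absolute survival, QALY and cost levels and between-arm
deltas — these depend on the unpublished life table/MRR schedule and on
the off-diagonal completion scheme, and the published ICER-plane fractions
(92.0/5.5/2.5% and 61/15/5/19%) inherit both dependencies, so they are
validated structurally (fractions sum to one, CEAC monotone, quadrant
logic exhaustive) rather than numerically. Problem sizes used by the
checks — 50,000 patients for the OI rate, 100,000 for oracle equivalence,
200,000 for demographics — were chosen to make 3-standard-error bands
narrow relative to the quantities checked.

Other known limitations: no within-cycle competing-risk correction (event
draws are ordered, not jointly modelled); second-line regimens are one
aggregate with a single flat utility; the synthetic life table is smooth
and lacks accident-hump and cohort effects of real national tables —
conclusions about absolute life expectancy should use a supplied real
table; and the model counts only each arm's primary AE as
treatment-emergent, matching how AE risks are parameterised.
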