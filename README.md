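# hivcea

Lifetime cost-utility microsimulation of first-line antiretroviral therapy
for HIV infection, from a third-party payer's perspective. The package is
aimed at health-economics analysts who want a fully inspectable,
patient-level Markov model — every transition rule, event risk, cost and
utility is a plain configuration value — rather than a black-box decision
tree.

## The model

Patients are simulated individually in 6-month cycles over eight health
states defined by CD4 cell count and viral-load (VL) detectability
(1: CD4 > 350, VL < 50 copies/mL … 8: CD4 < 50, VL ≥ 50). Three first-line
strategies are compared: twice-daily lopinavir/ritonavir (LPV/r),
once-daily atazanavir + ritonavir as observed in routine care (ATV+r 1),
and a trial-adjusted variant (ATV+r 2) whose transitions into detectable-VL
states are 19% less likely than under LPV/r.

Each cycle a patient may die (life-table mortality scaled by an HIV
mortality-rate-ratio), change state (semestral transition matrix), and
experience recurrent events: AIDS (per-state probability), coronary heart
disease (stratified by prior diabetes/CHD and reduced by the treatment's
effect on the TC:HDL cholesterol ratio — 14% less risk per unit decrement),
opportunistic infection (constant 1.76%/semester), chronic kidney disease
(risk ramping geometrically from 0.12% at cycle 1 to 2.9% [LPV/r] or 23.3%
[ATV+r] at cycle 40, frozen at its current value on switching), and the
arm's primary adverse event (diarrhoea for LPV/r, hyperbilirubinemia for
ATV+r). An adverse event, or a detectable viral load in two consecutive
semesters, moves the patient to an aggregate second line for life. Costs
(state-specific annual costs plus per-event costs, in euro) and utilities
(state-specific weights, with event- and CHD-specific decrements, worst
applicable weight per cycle) accrue per cycle, discounted at 3%/year.
Outcomes per arm are quality-adjusted life-years (QALYs), costs, cost per
QALY, and the incremental cost-effectiveness ratio (ICER) between arms:

ICER = (C_a − C_b) / (E_a − E_b)  [€ per QALY]

Only the matrix *diagonals* (probability of remaining in a state) are
published. The package reconstructs full row-stochastic matrices by
calibration: because ATV+r 2 is defined as LPV/r with transitions into
detectable states scaled by (1 − 0.19), each printed diagonal pair pins
down the LPV/r off-diagonal mass into detectable states,
`(diag_ATV+r2 − diag_LPV/r) / 0.19`; the remaining mass is spread by a
pluggable completion scheme. A probabilistic sensitivity analysis redraws
all Table-5-style parameters (beta/uniform/truncated-normal families) in an
outer loop and simulates both arms with common random numbers in the inner
loop, yielding ICER-plane clouds and cost-effectiveness acceptability
curves.

## Worked example

```r
library(hivcea)
params <- load_model_config()     # packaged base case
lpvr  <- simulate_arm("lpvr",  n = 20000, params = params, seed = 1)
atvr1 <- simulate_arm("atvr1", n = 20000, params = params, seed = 1)
print(lpvr)
compare_arms(lpvr, atvr1, wtp = 25000)
```

```
<cea_arm_summary> LPV/r  (n = 20,000, seed 1)
  Survival years (mean)                  31.233
  QALYs (mean, discounted)               14.751
  Per capita mean annual cost (EUR)      7855.46
  Lifetime cost per patient (EUR)        245351.63
  Total cost per QALY (EUR)              16633.43
  Years on first-line therapy (mean)     4.813
  ...
  OI events /1000 py                     35.4
<cea_comparison> LPV/r vs ATV+r 1 (WTP 25,000 EUR/QALY)
  delta cost:    -361.99 EUR
  delta QALY:    -0.1985
  ICER:          1823.36 EUR/QALY
  category:   sw_icer_below_wtp
```

LPV/r costs €362 less per lifetime here but yields 0.20 fewer QALYs; at
€1,823 saved per QALY forgone — far below the €25,000 threshold — the
comparator would be preferred in this run. The OI rate of 35.4 per 1000
patient-years follows directly from the constant semestral risk. Headline
survival/QALY levels and between-arm deltas depend on two inputs that were
never published (the national life table with its HIV mortality-rate-ratios
and the off-diagonal transition mass), so they are reconstruction-specific;
the vignette discusses which outputs are and are not anchored to printed
values.

A thin command-line front end is included:

```sh
Rscript inst/cli/run_cea.R compare --n 5000 --seed 1 --out results/
Rscript inst/cli/run_cea.R psa --outer 200 --inner 5000 --seed 1 --out results/
```

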