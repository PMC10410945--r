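---
title: "Methods: Markov cohort cost-effectiveness analysis in ceamarkov"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Markov cohort cost-effectiveness analysis in ceamarkov}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceamarkov)
```

## The model

`ceamarkov` implements a discrete-time Markov cohort model for two-arm
cost-effectiveness analysis. A closed cohort of `N` persons (default
1000) enters a small ordered state space in the entry state; once per
annual cycle the occupancy row vector is multiplied on the right by a
row-stochastic transition matrix (rows are origin states, columns
destinations — stated explicitly to avoid transposition bugs). Absorbing
states (death) carry identity rows, zero cost and zero utility.
Occupancy is tracked as expected fractional persons, the standard cohort
expectation; the individual-level view is covered by the
microsimulation oracle (`microsimulate()`), which simulates categorical
state paths and converges to the cohort expectation by the law of large
numbers.

The shipped scenario (`alzheimer_scenario()`) models mild Alzheimer's
disease: states mild → moderate → severe → death, published annual
transition probabilities, annual state costs of $3,140 / $9,460 /
$16,956 for care under standard of care and $22,000 for the drug in the
mild state, utilities 0.73 / 0.69 / 0.27, a 5-year horizon of 1-year
cycles, a 6% annual discount rate and a willingness-to-pay threshold of
$28,617/QALY (three times GDP per capita, the WHO rule). The 1-year
cycle length is the only reading consistent with annual transition
probabilities and a 5-year horizon of 5 cycles.

## The treatment effect

The comparator arm applies a relative risk `RR = 0.6` to the mild-state
row. Published verbal descriptions of this arithmetic are ambiguous, so
three conventions are implemented (`treatment_effect()`):

* `scale_all_exits` — all exits (progression and death) × RR, the
  self-transition takes the rest; this realises a reading where the
  mild→death probability also falls.
* `progression_only` — only progression to worse living states × RR;
  death unchanged; the standard epidemiological reading.
* `complete_arrest` — the best-case assumption that therapy completely
  stops progression: progression zeroed, death × RR, self-transition
  takes the remainder.

All three keep the row stochastic; `RR = 1` is the exact identity for
the two scaling conventions.

## Reward accrual, discounting and convention calibration

Cycle rewards can be accrued on begin-of-cycle, end-of-cycle or
half-cycle-corrected occupancy. Discounting follows
`(1 + r)^-(cycle - 1)` so the first year is undiscounted (an
exponent-of-cycle alternative sits behind a flag in `discount_spec()`).
Totals are reported per person; the per-cycle table carries cohort
totals too.

Because the published analysis does not state its accrual timing,
discount application, RR arithmetic or whether the drug price replaces
or adds to the mild-state care cost, `calibrate_conventions()`
enumerates the full 3 × 3 × 2 × 2 grid and ranks each combination by
total relative error against the four published base-case numbers (SoC
cost $21,292.16, Aducanumab cost $98,068.49, SoC 2.94 QALY, Aducanumab
3.58 QALY). The winner — complete arrest, begin-of-cycle accrual, no
discounting, drug price replacing the mild care cost — is frozen in the
shipped YAML config and recorded in every run manifest, so the
convention choice is visible rather than silently hard-coded.

```{r calibration}
cal <- calibrate_conventions(alzheimer_scenario())
head(cal, 3)
```

The calibrated model reproduces the reference arm closely (cost −1.2%,
QALY +0.3%) and the comparator arm to about 5%. The published ICER of
$119,482.80/QALY is *not* reproducible from the published inputs: it
implies an incremental gain of 0.64 QALY, i.e. a comparator arm
accruing ≈4.9 of 5 possible life-years in the mild state (annual
survival ≈0.99), whereas the published mild→death probability of 0.055
bounds annual survival at 0.967 even under complete arrest (our best
ΔE ≈ 0.47, ICER ≈ $175,527). The package reports what the inputs imply;
the direction of the decision (far above threshold, not cost-effective)
is unaffected, and every downstream conclusion the package computes
agrees with the published ones qualitatively.

## Uncertainty analysis

**One-way DSA** (`one_way_dsa()`): each parameter in turn is set to its
low/high value with the rest at base, and the ICER is recorded; entries
are sorted by spread for the tornado plot. Defaults: costs and
utilities vary ±1.96 standard errors (SE = 20% of the mean for costs,
10% for utilities, the conventional assumption when primary variance
data are unpublished); each non-zero off-diagonal transition
probability varies ±1.96 × 10% of itself, re-balanced through the
origin state's self-transition (an invalid row is an error, not a
silent fix); the discount rate spans the published 3–9% range. The
discount-rate entry evaluates with discounting *enabled* at each end —
otherwise the parameter would be inert under the calibrated
undiscounted base case.

**PSA** (`run_psa()`): a single-level parameter-sampling Monte Carlo
with 1000 iterations by default. Utilities draw from beta and costs
from gamma distributions parameterised by method of moments
(`parameterize_beta()`, `parameterize_gamma()`), with SEs equal to the
uncertainty scales above; care costs shared by both arms share one draw
per iteration so the arms stay correlated. Each uncertain transition
row is drawn whole as a Dirichlet vector with `alpha = row × k`,
`k = 1/s² − 1`, which keeps the row stochastic, preserves component
means and leaves structural zeros at zero; element-wise beta draws with
renormalisation would distort the row means, which is why the joint
draw is the default. The treatment effect is applied to the *sampled*
base matrix, so both arms share the drawn natural history. A single
seeded generator (scoped with `withr::with_seed`, so the global RNG is
untouched) drives all draws; the seed is recorded in the cloud's
attributes and in the run manifest. The CEAC grid defaults to $0 to
$150,000/QALY in $500 steps, covering the region where acceptability
becomes positive.

Degenerate inputs are handled exactly: uncertainty scale 0 returns the
mean (so a zero-variance PSA collapses onto the deterministic base
case), zero incremental effect yields an "undefined" verdict rather
than a division, and equal dominance rules follow the usual sign
conventions on (ΔC, ΔE).

## The synthetic-scenario generator

`generate_scenario()` draws random valid scenarios: symmetric unit-sum
Dirichlet(1) rows for non-absorbing states, an absorbing terminal
state, utilities in \[0, 1\] (non-increasing in severity when
`progression_ordering` is set) and positive costs (non-decreasing), a
drug-style comparator cost in the entry state, RR ~ U(0.2, 1), discount
rate ~ U(0, 0.09). It emulates the *structure* the analysis assumes —
row-stochasticity, absorbing death, ordered rewards — not the
epidemiology of any real disease: rows are exchangeable rather than
progressive, so passing property tests demonstrates correctness of the
arithmetic (conservation of cohort mass, monotone absorption, validity
under treatment adjustment, oracle agreement), not calibration to real
cohorts. Problem sizes used in the shipped test-suite sweeps: 1000
generated scenarios for conservation, 20 scenarios × 200,000 simulated
individuals for the microsimulation oracle (3-standard-error
agreement), chosen to make Monte-Carlo error small relative to the
quantities checked.

## Known limitations

* Time-constant transition probabilities; no age-dependence, tunnel
  states or background-mortality life tables (death is folded into the
  transition matrix).
* The published analysis's variance/CI inputs are unreported; all
  uncertainty scales here are declared assumptions, so exact published
  PSA percentages (e.g. acceptability at specific six-figure
  thresholds) are checked qualitatively (monotone, positive above
  ~$100k), not numerically.
* Two-level ("sample exchange") sampling from the original software is
  not re-implemented; iteration-level outputs are the reported unit.
* The published comparator QALY total (and hence the exact ICER) is not
  derivable from the published inputs, as quantified above.
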