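---
title: "A Markov cohort model for the cost of unintended pregnancies from contraceptive drug-drug interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for the cost of unintended pregnancies from contraceptive drug-drug interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddiburden)
```

## The problem and the model

Oral contraceptives (OCs) are metabolised by hepatic cytochrome P450
enzymes. Co-medications that induce those enzymes — certain antiepileptics,
antiretrovirals and rifamycin antibiotics — lower hormone exposure and can
cause contraceptive failure even in fully adherent women. `ddiburden`
quantifies the resulting incremental burden for a healthcare payer: how many
additional unintended pregnancies (UP), and at what direct medical cost, a
cohort of OC users incurs when an enzyme-inducing co-medication raises the
failure rate.

The engine is a five-state absorbing Markov cohort model. All women start in
an "initial method" state (on OC, not pregnant). Each monthly cycle a woman
fails contraception with probability $p_{\text{fail}}$ and, if so, moves
directly to one of four absorbing outcome states — birth, induced abortion,
spontaneous abortion or ectopic pregnancy — with probability
$p_{\text{fail}} \cdot p_{\text{outcome}}$. Unintended pregnancy itself is
not a state: gestation timing is not modelled, and a woman who reaches an
outcome never re-enters (no switching, discontinuation or repeat
pregnancies).

Annual failure rates are Pearl indices, failures per 100 woman-years. They
are converted to a per-cycle probability by the constant-hazard transform

$$p = 1 - \exp(-r\,t),$$

with $r$ the annual rate (divided by 100 only at this point; configurations
store rates exactly as published) and $t$ the cycle length in years. The
cohort trace multiplies the occupancy row by the transition matrix each
cycle; expected outcome counts are the absorbing-state occupancies at the
final cycle.

**No half-cycle correction is applied.** With a single transient state and a
constant hazard, whole-cycle jumps make the 12-cycle cumulative failure
exactly $1 - \exp(-r \cdot 1\,\text{yr})$, which is what the closed-form
oracle `closed_form_up()` computes and what the published counts reflect. A
half-cycle correction would be defensible for a general cost-effectiveness
model but would break the equivalence that makes the trace analytically
verifiable.

## Parameters

The shipped base case (`ddi_example_config()`) encodes:

* **Failure rates** (per 100 woman-years): perfect-use OC alone 0.3;
  OC + enzyme inducer 2.3 (95% CI 1.9–2.8); OC + enzyme-neutral drug 1.6
  (95% CI 1.4–1.8). The CI bounds come from a claims-database analysis and
  drive the range columns of the results, not probabilistic intervals.
* **Outcome distribution**: birth 0.492, induced abortion 0.350, spontaneous
  abortion 0.153, ectopic pregnancy 0.005 (sum constrained to 1 within
  1e-9).
* **Unit costs** (2020 USD per event, payer perspective): literature
  summaries as median (min–max), e.g. birth 12,953 (5,270–28,664). Costs are
  not discounted within the one-year horizon.
* **Mistimed-birth adjustment**: fraction mistimed $f = 0.60$, discount rate
  $r = 0.03$, delay $d = 2$ years. The adjusted birth unit cost is
  $c \times (1 - f/(1+r)^d)$ — a mistimed birth would have happened anyway
  $d$ years later, so only the discounted difference is attributed to the
  failure.
* **Run settings**: closed cohort of 1,000 women, 12 cycles of 1/12 year.

### The two adjusted-birth-cost numbers

The configuration also carries a pre-tabulated adjusted birth-cost summary
(median 5,497, range 2,290–12,453) as published. Applying the adjustment
formula to the unadjusted median 12,953 instead gives 5,627.33, and it is
this formula value that is arithmetically consistent with every adjusted
cost cell of the published results table (the published range endpoints
2,290 and 12,453 *are* the formula applied to 5,270 and 28,664, to the
printed dollar). The likely origin of the 5,497 median is taking the median
of individually adjusted source costs rather than adjusting the median; the
source does not say. The engine therefore always recomputes the adjustment
from the unadjusted costs via `adjust_birth_cost()`, and the pre-tabulated
summary is retained in the configuration purely as documentation.

## Costing and incremental comparison

`total_costs()` multiplies **unrounded** expected counts by unit costs,
independently for the median, minimum and maximum columns, and sums over
outcomes. Rounding happens only at display time, half away from zero — the
published table shows 0 expected ectopic pregnancies next to a non-zero
ectopic cost, which is only possible if unrounded expectations flow into the
cost arithmetic. (The rounding rule itself is not stated in the source; all
published counts are consistent with either half-up or half-even, and half
away from zero is adopted and used everywhere.)

`compare_strategies()` implements deterministic interval propagation:
the median difference is taken at point-estimate rates, the lower bound is
the comparator's minimum-cost total at its lower-CI rate minus the
reference's minimum-cost total (at its lowest available variant), and
symmetrically for the upper bound. These are bound-for-bound envelopes, not
confidence intervals; it is the only reading under which the published
incremental ranges equal differences of the published per-strategy cells.
The headline count difference uses integer-displayed counts (rounded and
unrounded counts give the same values here).

## Scenarios

1. **Typical use** (`typical_use_rates()`): the OC-alone rate is replaced by
   the typical-use rate (7.2) and every co-medication rate is raised by the
   typical-minus-perfect increment (6.9), point estimates and CI bounds
   alike — the source is silent on the bounds, and the additive shift
   preserves the published CI widths. The reported 3.8-fold rise in inducer
   pregnancies is reproduced from integer-displayed counts (unrounded counts
   give 3.87).
2. **Abortion-share shift** (`abortion_shift()`): the induced-abortion share
   is set to a target (e.g. a state-specific share) with spontaneous and
   ectopic shares held at base values and birth absorbing the remainder.
   The hold-constant rule is stated in the source only for the age-specific
   scenario; applying it here too is this package's documented
   interpretation, and the only stated redistribution mechanism.
3. **Age-specific mixes** (`age_specific_runs()`): one full evaluation per
   age-group outcome mix at fixed cohort size, with the spontaneous and
   ectopic shares required to stay at base values (a deliberate override is
   possible with a warning).

The external inputs of scenarios 2–3 (state abortion shares, age-group
mixes) are not published numbers; they are accepted only as user
configuration, and the package's guarantees for these scenarios are
structural: transformations are pure, redistributions sum to 1, and the
total number of unintended pregnancies is invariant to the outcome mix
(the split does not enter the failure dynamics).

## The microsimulation oracle

The deterministic engine is validated by double implementation:
`simulate_cohort()` realises the same process at the individual level.
Each woman's failure cycle is drawn from the geometric distribution implied
by the per-cycle probability (inverse-CDF on a uniform), her outcome from
the categorical outcome distribution, and her cost from either a point mass
at the median unit cost (default, matching the deterministic median
pathway) or a triangular(min, median, max) spread (an exploratory extension
beyond the published analysis). Every woman consumes exactly three uniforms
from one seeded stream, so results are bit-reproducible and independent of
evaluation order. Women are independent, matching the cohort model's
implicit assumption.

`convergence_report()` compares simulated counts (and, under point-mass
costing, total cost) against the deterministic expectations rescaled to the
simulated sample size, using binomial/multinomial standard errors; |z| > 3
flags an inconsistency. The test suite exercises this at 1,000, 100,000 and
500,000 women (a 500,000-woman run takes well under a second) together with
a chi-square goodness-of-fit on the outcome split at alpha = 0.01, and a
power check that expectations computed at twice the true rate are rejected.

What the simulation emulates is exactly the model's world: constant hazard,
immediate outcome assignment, independence, no adherence dynamics or
inter-individual pharmacokinetic variability. Agreement between the two
implementations therefore validates the arithmetic, not the epidemiology;
real-world failure rates are heterogeneous across drugs, doses and
populations in ways neither implementation represents.

## Numerical choices and edge cases

* Tolerances: row-stochasticity of the transition matrix within 1e-12;
  outcome-share and cohort-conservation checks at 1e-9; trace/closed-form
  equivalence at 1e-9 relative. Comparisons against published dollar cells
  use 0.1% relative tolerance, absorbing the rounding of published inputs
  (rates to one decimal, costs to whole dollars).
* Degenerate inputs: a zero failure rate yields an identity transition row,
  zero events and zero costs end to end; a numerically certain per-cycle
  failure sends the whole cohort to outcomes in cycle one.
* Counts are validated to display as published: e.g. the inducer strategy's
  0.114 expected ectopic pregnancies display as 0 while still contributing
  their expected cost.
* `cycle_length` may be written as the string `"1/12"` in configurations so
  the monthly cycle is exact rather than a truncated decimal.
* Configuration files carry a `schema_version` and unknown keys are
  rejected, so typos fail loudly rather than silently falling back to
  defaults.

## Limitations

The model inherits the published analysis' scope: direct medical costs of
four pregnancy outcomes only — no adverse-event, perpetrator-drug
efficacy-loss, indirect, downstream or societal costs; no contraceptive
switching or discontinuation; a constant failure rate per strategy; all
pregnancies in the horizon assumed unintended. The range columns are
deterministic envelopes over published min/max unit costs and CI bounds,
not uncertainty intervals with coverage guarantees.
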