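---
title: "A Markov cohort model for toileting and containment care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for toileting and containment care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tccmodel)
```

## The decision problem

Most nursing-home residents with urinary or faecal incontinence are managed
with a mix of assisted toileting and absorbent products ("toileting and
containment care", T&CC). How that mix is chosen affects residents' quality
of life, their skin health, adverse events such as urinary tract infections
and pressure ulcers, staff time, product consumption and waste. `tccmodel`
implements a cohort state-transition model to compare two care strategies —
here, conventional continence care versus care planning informed by a
sensor-based digital bladder diary (a digital health technology, DHT) — in
terms of lifetime discounted quality-adjusted life years (QALYs), costs by
category, care hours and disposal mass.

## Model structure

The model has three dimensions:

* **Care-need groups** `G1`–`G6`: increasing dependence on caregivers,
  driven by cognition and mobility. Disability never improves; the group
  transition matrix is upper triangular. The bundled residential case study
  uses `G2`–`G6` (care-independent `G1` residents do not live in
  residential care), but the engine accepts any subset.
* **Care stages** `CS1`–`CS3`: from mainly successful toileting to mainly
  containment, operationalised by the total 24-hour Rothwell absorbency of
  the products used (`classify_care_stage()`; band endpoints are assigned
  to `CS2` so the three stages partition the line — the published
  definition prints strict inequalities only for the outer stages).
* **Skin-health levels** `SHL1`–`SHL5`: none to very severe
  incontinence-associated dermatitis.

Only the first two dimensions are Markov states. Skin health is assigned
anew each cycle as a strategy- and care-stage-specific mixture: since
individuals *are assigned* a skin level given their care stage every cycle,
skin health is memoryless and affects outcomes (utilities, treatment costs)
but never the dynamics. This reduces the state space from 90 to
`5 groups x 3 stages + dead = 16` states.

Cycles are 2 months (1/6 year); the cohort starts at age 86 and is followed
until extinction (survival below `survival_epsilon = 1e-6`, reached after
about 26 years; a 240-cycle cap guards against non-absorbing inputs).
Mortality depends on an age band (65–74, 75–84, 85–94, 95+) and a group
class (`G1`, `G4`, or the shared class for `G2/G3/G5/G6`); the cohort's
scalar age advances each cycle, so the band switches mid-run. Incontinence
severity itself carries no excess mortality, which is why both strategy
arms accumulate identical life years.

### Within-cycle composition

The one-cycle matrix composes death, the group move and the care-stage
move as

\[ P((g,c) \to (g',c')) = (1 - m_g(a))\; P_{\text{group}}(g \to g')\;
   Q(c \to c'), \]

with the dead column receiving \(m_g(a)\). Two readings of \(Q\) are
implemented and isolated behind `build_cycle_matrix(group_change_cs = )`:

* `"independent"` (default): every survivor's care stage follows the
  strategy's care-stage transition row, regardless of the group move.
* `"shift"`: group-movers skip the care-stage row and instead keep their
  stage with probability 0.10 or move one stage worse with probability
  0.90 (the worst stage absorbing), a literal reading of the assumption
  that unadjusted care deteriorates with rising disability.

The case study's source material states the 10%/90% assumption but only
publishes the *combined* group-by-stage matrices in supplementary files
that are not redistributed here, together with the resulting cohort
trajectories. The two readings disagree materially: under `"shift"` the
2-year DHT-arm share in `CS3` is 21% of survivors, 6 percentage points
above the published 15%, while `"independent"` reproduces every published
2-year share within 0.8 points (conventional 11.6/49.0/39.4 vs published
12/49/40; DHT 21.0/64.8/14.2 vs 21/64/15). We therefore treat the product
structure as what the original computation did and make it the default;
the `"shift"` composition remains available and is exercised in the test
suite, including against a per-individual microsimulation oracle.

### Initial state

The initial joint distribution is the product of the group and care-stage
margins (the case study measured the same care-stage mix in every group),
with the dead state empty.

## Outcomes

All streams are accumulated with a trapezoid half-cycle correction: cycle
boundaries get weight 1/2 at both ends of the horizon and 1 in between,
each boundary discounted at its own time point,
\(d_t = (1+r)^{-t\,\Delta t}\) with \(r = 0.05\)/year. Under this
convention the bundled mortality inputs give a mean undiscounted survival
of 2.32 years against the externally reported 2.34; end-of-cycle counting
would give 2.25 and start-of-cycle 2.42, so the half-cycle convention is
the one consistent with the reported lifetime. (The separately reported
"57% alive at two years" is not reproducible from the bundled per-cycle
mortality table — any composition of those inputs yields about 42% — and
is not used by this package.)

**QALYs.** A state's utility is the group baseline minus the care-stage
decrement minus the expected skin decrement under the per-cycle mixture;
adverse events (toileting-related fractures, zero-rated for the immobile
`G5`/`G6`; UTI; constipation; pressure-ulcer categories I–IV, category I
carrying no decrement) subtract `rate x decrement` per cycle, i.e. each
event depresses utility for one cycle — the simplest rate-based reading of
a "temporary" loss. Decrements are stored as non-negative magnitudes. The
reported decomposition `total = care-stage component - skin loss - event
loss` is accumulated unclipped so it is additive to 1e-9; the per-state
utility helper clips at zero, which none of the bundled inputs approach.
The care-stage component includes the group baseline (this is the
convention under which the three components sum to the published totals).

**Costs** (seven categories; the bundled fixture is priced in CAD 2020):
labour (task frequency x minutes x staff x blended formal/informal wage),
absorbent products (daily count x price), perineal hygiene (one
application per product change), disposal (dry product weight x tariff —
an acknowledged underestimate of used-product weight), care consequences
(event rate x cost per occurrence), severe-skin treatment (each cycle's
`SHL5` assignment triggers one 7-day episode, one 1-minute application per
product change plus consumables), and technology acquisition (per
person-year, DHT arm only). Costs are discounted; care **hours** and
disposal **kg** are physical totals and accumulate undiscounted.

## Parameters

| Parameter | Default | Units / notes |
|---|---|---|
| `cycle_length` | 1/6 | years; 2-month reassessment interval |
| `discount_rate` | 0.05 | per year, costs and effects alike |
| `start_age` | 86 | cohort mean age at entry |
| `survival_epsilon` | 1e-6 | extinction threshold |
| `max_cycles` | 240 | horizon cap (40 years) |
| `row_tol` | 0.02 | tolerated row-sum deviation before renormalisation |
| `group_change_cs` | `"independent"` | within-cycle composition (above) |
| `informal_share` | 0 | residential case study: all care formal |

Printed source tables are rounded, so transition rows may sum to slightly
off 1 (one bundled row sums to 1.01, another to 0.995); rows within
`row_tol` of 1 are renormalised on load, anything further is rejected as a
transcription error.

### The economics fixture is synthetic

The case study's unit costs and resource-use frequencies live in
supplementary files that are not redistributed. The bundled
`economics_synthetic.yaml` is a clearly flagged placeholder with plausible
CAD-2020 values (chosen once; e.g. $0.75/min blended staff cost,
$250/person-year technology price, group-invariant task frequencies), so
the entire cost pathway is exercisable and property-tested — but cost
results obtained with it are illustrative, not a reproduction of the
published cost table. Effect-side results never touch it.

## Uncertainty analysis

**One-way (tornado).** Every non-fixed scalar parameter is set to its 95%
bounds — the tabulated CI for mortality, otherwise `mean ± 1.96 se` with
`se = 0.2 mean` — holding the rest at base. Held fixed: cycle length,
horizon, discount rate, the structurally-zero CS1/SHL1 decrements,
zero-mean rates, and `G2`–`G3` staffing counts.

**Probabilistic.** All non-fixed parameters vary simultaneously:

* moment-matched **Beta** for probabilities reported as scalars (event
  rates, event decrements), `se = 0.2 mean`;
* moment-matched **Gamma** for costs and resource use, `se = 0.2 mean`;
* **Normal** for age, mortality (SE from the tabulated CI) and
  group/stage/skin utility decrements, truncated to the admissible range
  by resampling (how the original analysis handled out-of-range draws is
  unstated; resampling keeps draws in range at the price of a small mean
  shift near a bound);
* **Dirichlet** for each initial distribution and each transition row.

Two Dirichlet details are this package's own choices. The concentration is
set so the largest-mean component has SE equal to 20% of
`min(mean, 1 - mean)`: a plain 20%-of-mean target is infeasible for rows
whose largest entry exceeds 0.96 (several group and skin rows) and yields
implausible bathtub-shaped draws for near-unit probabilities, while the
symmetric rule reduces to the 20% convention away from the boundary.
Degenerate rows (an entry equal to 1) stay fixed. Second, the start age is
drawn with SE 1 year — the order of a trial cohort's standard error of its
mean age — rather than the 20% default, which would imply a ±34-year
confidence band on a measured mean age.

Mortality, group transitions, initial distributions and utilities are
drawn once per iteration and shared by both arms; arm-specific tables
(care-stage transitions, skin mixtures, event rates, cost inputs) are
drawn independently per arm. The default is 5,000 iterations with a
recorded seed, enough to put the Monte-Carlo SE of the mean incremental
QALYs near 1e-4 and of any quadrant share below 0.8 points. With
`se_scale = 0` every draw collapses onto the base values, which the test
suite uses to confirm the PSA degenerates to the deterministic result.

The PSA's mean incremental QALYs with the bundled effect-side tables is
0.0141 against a deterministic 0.0143 — the mild concavity is the
opposite sign of the +0.001 gap in the externally reported pair
(0.016 probabilistic vs 0.015 deterministic), which will reflect the
original, unpublished concentration choices.

The cost-effectiveness acceptability curve reports, for each
willingness-to-pay threshold \(\lambda\), the fraction of draws with
non-negative net monetary benefit \(\lambda \Delta E - \Delta C\); its
value at \(\lambda = 0\) equals the probability of cost savings.

## The synthetic parameter generator

`generate_synthetic_params()` exists to exercise every code path with
valid random inputs. Without a template it draws uniform-simplex rows
(respecting the no-improvement structural zeros of the group matrix) and
broad plausible scalars; with a template it recentres all draws on the
template's values using the PSA families, so ensemble means converge to
the template. What it deliberately does *not* emulate: correlation between
a resident's group and care stage at entry, time-varying intervention
effectiveness, or excess mortality with incontinence severity — passing
tests on synthetic sets therefore demonstrate engine correctness
(conservation, monotonicity, additivity, oracle agreement), not clinical
realism of any particular draw.

## Numerical choices and degenerate inputs

* Transition matrices are rebuilt only when the cohort crosses a mortality
  age band; rows are verified row-stochastic to 1e-12 at build time and
  occupancy mass is conserved to 1e-9 per cycle.
* A cohort that is not extinct at `max_cycles` yields a recorded
  non-convergence warning rather than an error (zero-mortality inputs are
  legal and useful in tests).
* Trajectories carry a content fingerprint of the parameter set; the
  outcome accumulators refuse a trajectory produced under different
  parameters.
* `normalize_rows()` is idempotent; validation reports renormalisable rows
  as warnings and everything else as errors, and never mutates its input.
* Test and example problem sizes: the microsimulation oracle uses 100,000
  individuals over 12 cycles (3 Monte-Carlo SEs per state); template-mean
  checks use a few hundred draws; in-suite PSA checks use up to 5,000
  iterations. A full deterministic run takes well under a second and the
  5,000-iteration effect-side PSA under a minute on one core.

## Known limitations

* The within-cycle composition is a reconstruction (see above); both
  readings are shipped, and conclusions that hinge on group-mover
  care-stage dynamics should be checked under both.
* Care-stage transition probabilities measured over 8 weeks are applied
  per 2-month (~8.7-week) cycle without rate conversion, matching the
  original analysis; the mismatch is a consistent small bias, not noise.
* DHT event-rate reductions come from a single expert; their PSA spread
  uses the default 20% SE.
* Skin health being memoryless, chronic dermatitis episodes spanning
  cycles are not represented; severe-skin treatment is costed as one
  7-day episode per cycle in `SHL5`.
* The disposal stream uses dry product weight and a flat per-kg tariff; no
  container or collection-schedule modelling.
* The bundled cost fixture is synthetic (above); published cost totals are
  not reproduced by design.
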