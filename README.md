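# tccmodel

A Markov cohort model for the health-economic evaluation of **toileting and
containment care** (T&CC) strategies in older adults with incontinence.
The package is aimed at health-economic modellers and HTA analysts who want
a transparent, scriptable engine for comparing continence-care strategies —
for example a sensor-based digital bladder diary that informs person-centred
care plans versus conventional containment-focused care in nursing homes.

## The model in brief

A cohort is followed in 2-month cycles over states
`(care-need group G2..G6) x (care stage CS1..CS3)` plus an absorbing dead
state. Groups encode rising dependence on caregivers and only ever worsen;
care stages run from mainly successful toileting (CS1) to mainly
containment (CS3) and are operationalised by the total 24-hour Rothwell
absorbency of the products used. Skin health (SHL1..SHL5) is *not* a Markov
state: each cycle survivors in a care stage are assigned a skin level from
a strategy-specific mixture, so it affects outcomes but not dynamics.

One cycle composes mortality, the group move and the care-stage move:

    P((g,c) -> (g',c')) = (1 - m_g(age)) * P_group(g -> g') * P_cs(c -> c')

with mortality m\_g(age) read from an age-band x group-class table.
Discounted QALYs, costs (seven categories), care hours and disposal mass
are accumulated with trapezoid half-cycle correction:

    E = sum_t w_t (1+r)^(-t*dt) * occ_t' u * dt,   w_0 = w_T = 1/2

where `u` holds per-state utilities (group baseline minus care-stage and
expected skin decrements, minus adverse-event disutility rates). Strategies
are compared by incremental costs and effects (dominance or ICER), with
one-way (tornado) sensitivity analysis over 95% parameter bounds and a
probabilistic sensitivity analysis drawing Beta/Gamma/truncated-Normal
scalars and Dirichlet transition rows (SE = 20% of the mean where no CI is
reported), summarised on the cost-effectiveness plane and as a
cost-effectiveness acceptability curve.

A Canadian nursing-home case study (CAD 2020, start age 86, 5% discounting)
ships with the package: all effect-side tables are bundled, while the
cost-side unit costs and frequencies are a clearly labelled **synthetic
placeholder** fixture (the originals live in unreleased supplementary
data), so cost results are illustrative while effect results are not.

## Worked example

```r
library(tccmodel)

ps <- load_case_study()               # effect-side tables, both arms
ce <- run_deterministic(ps)
ce
#> <tcc_ce> DHT vs conventional care
#>   incremental QALYs: +0.0143
#>   result: effect-only comparison (no economics block)

ce$qaly$conventional
#> <tcc_qaly> conventional
#>   QALYs 0.8633 = care stage 0.8913 - skin 0.0043 - consequences 0.0238
#>   life years: 2.089 discounted, 2.321 undiscounted

traj <- run_cohort(ps, "dht")
round(100 * surviving_cs_shares(traj, cycle = 12), 1)
#>  CS1  CS2  CS3
#> 21.0 64.8 14.2
```

Read: over a mean remaining lifetime of 2.32 years the digital technology
gains 0.0143 discounted QALYs per resident, mostly through better toileting
success — after two years 21% of its surviving cohort is managed mainly by
toileting and only 14% mainly by containment, against 11.6% and 39.4%
under conventional care (`surviving_cs_shares(run_cohort(ps,
"conventional"), 12)`), with 93.8% vs 98% of survivors free of skin
problems (`surviving_shl_shares()`).

With the synthetic economics fixture the full cost pathway runs too:

```r
ps_cost <- load_case_study(economics = "synthetic")
run_deterministic(ps_cost)            # adds the seven-category cost breakdown
run_psa(ps_cost, n_iter = 5000, seed = 1)   # CE plane + quadrant shares
```

A thin command-line interface wraps the same functions
(`inst/cli/tccmodel run --economics synthetic --out results/`), writing CSV
tables plus a JSON manifest (fingerprint, seed, options) per run; see
`?tcc_main`.

## Package layout

* `R/` — parameter containers and validation, the transition engine,
  QALY/cost/resource accumulators, OWSA/PSA/CEAC, I/O and the CLI
* `inst/extdata/` — the case-study fixture and the synthetic economics
  placeholder (YAML, with per-block provenance comments)
* `vignettes/tcc-cohort-model.Rmd` — the methods write-up: model
  assumptions, conventions, uncertainty families, limitations
* `tests/testthat/` — unit, property and acceptance tests, including an
  independent 100,000-person microsimulation oracle for the engine
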