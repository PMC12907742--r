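---
title: "A cohort Markov model of Alzheimer's disease progression and care costs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cohort Markov model of Alzheimer's disease progression and care costs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adcohort)
```

## The model and its assumptions

`adcohort` projects the UK (or any configured) population through five
mutually exclusive states — cognitively unimpaired, MCI due to AD, and
mild, moderate and severe AD dementia — in annual cycles, stratified by
5-year age band (0–4 … 100+) and sex. The Markov assumptions are the
standard ones: the process is memoryless, transition probabilities are
identical for everyone in a state and constant over calendar time, and the
states are exhaustive and mutually exclusive. Backward transitions
(moderate → mild, severe → moderate) are allowed; they represent
misclassification of dementia staging rather than genuine clinical
reversal.

Two structural choices matter most:

* **The unimpaired state is a residual.** Each projected year, the
  unimpaired population is recomputed as the national population
  projection minus the four disease states. Background (non-AD) mortality,
  migration and births therefore never appear explicitly — they are
  absorbed by the projection — while the disease states carry their own
  explicit mortality probabilities. This avoids double-counting deaths but
  means the model is only internally consistent while disease-state
  occupancy stays below the projection in every cell (see *Degenerate
  inputs* below).
* **Disease-state transition probabilities are age-invariant** except the
  incidence of MCI due to AD, which rises steeply with age. This mirrors
  the structure of the published estimates available for such models; it
  is also the model's weakest approximation at very old ages, where
  all-cause mortality far exceeds any age-invariant disease-state rate.

### Cycle order

Within one annual cycle the engine applies, in this fixed order:
disease-state transitions (including disease mortality) → incidence of MCI
due to AD out of the unimpaired population → cohort ageing → residual
recomputation. The published description of such spreadsheet models does
not pin down an order; a fixed documented order is required for exact
reproducibility, and this one applies incidence to the start-of-year
unimpaired stock before any ageing.

### Ageing

Each 5-year band passes 1/5 of its surviving occupants to the next band
per annual cycle; the open 100+ band retains its occupants. This is the
standard steady-flow approximation for banded cohort models. An
alternative reading — re-anchoring disease prevalence by age each year —
would tie the age profile to the baseline prevalence forever and make
incidence irrelevant; we reject it. Consequence: disease states age
through bands while the unimpaired state is re-derived from the
projection, so the disease age profile gradually shifts old relative to
baseline prevalence, which is the intended behaviour of a progression
model.

## Parameters

The packaged bundle `reference_parameters()` contains published UK
estimates, all provenance-tagged:

* AD dementia prevalence by band and sex, MCI-due-to-AD prevalence and
  incidence by band (age rows 30–34 … 100+; bands below 30 carry zero
  prevalence and incidence because no estimates exist below 30).
* Severity splits of prevalent AD dementia for four coarse age groups
  (35–64, 65–74, 75–84, 85+), mapped to 5-year bands by containment; the
  30–34 band uses the 35–64 row. The published rows are two-decimal
  percentages and sum to 99.99–100.01 %; validation accepts row sums
  within 5e-4 of 1, and the initialisation residual is computed against
  the summed states so population conservation is exact regardless.
* Per-person-per-year costs: all-England HCRU by band and sex;
  all-severity AD HCRU by band (identical across sexes, stored once);
  general social care (£0 under 18, £200.26 for 18–64, £499.89 for 65+,
  with the straddling 15–19 band taking the adult rate); AD social care by
  sex (£12,526 male, £12,480 female) multiplied by stage ratios and by the
  48 % formal social-care utilisation proportion. Severity cost ratios
  scale the all-severity AD cost (health 0.5548/1.4829/1.7597, social
  0.4261/1.7049/1.7622 for mild/moderate/severe). England HCRU values for
  bands below 30 extend the 30–34 value downward; these cells never touch
  disease states and cancel in all offset outputs. MCI due to AD is costed
  at general-population rates: the stage ratios cover dementia severities
  only, so AD-specific costs attach to dementia states alone.
* Follow-up visit unit costs: £33 primary care, £465 specialist (memory
  clinic). Currency is fixed at 2019 GBP and future costs are not
  discounted; per-person costs are held constant over the horizon.

**Transition probabilities between disease states are not published in
this parameter set.** They are mandatory user inputs; the shipped defaults
(`placeholder_transitions()`) are illustrative placeholders chosen inside
clinically plausible ranges for biomarker-confirmed cohorts — progression
0.35 (MCI → mild), 0.45 (mild → moderate), 0.35 (moderate → severe),
backward 0.05 on both edges, mortality 0.10/0.12/0.20/0.30 per year from
MCI/mild/moderate/severe — with two additional requirements the defaults
must satisfy by design: disease occupancy stays well below the projection
in every cell (no residual clamping in reference runs), and the scenario
economics sit in the regime where the per-treated-person-year gross saving
exceeds the specialist follow-up cost, so that care-model and uptake
comparisons are meaningful out of the box. They are tagged `"placeholder"`
in the provenance log and should be replaced for substantive use.

## DMT scenarios

A scenario is efficacy × uptake schedule × care model × launch year.
Efficacy `e` multiplies the two forward edges out of the treated states
(MCI → mild and mild → moderate) by `1 − e·f(y)`, where `f(y)` is the
treated fraction — uptake ramping linearly from 0 at the ramp start (2025)
to its maximum (58 % high, 25 % low) at the ramp end (2034), constant
after. This scaling is exactly the population-weighted mixture of treated
(`p(1−e)`) and untreated (`p`) flows, so no individual tracking is needed;
people transitioning backward into mild remain covered by the same
fraction (treatment is memoryless). Efficacy touches neither mortality nor
backward edges nor the moderate → severe edge (moderate AD is not
treatment-eligible). The eligible population is the MCI plus mild AD
count; treated(y) = uptake(y) × eligible(y); new starters are the
year-on-year increase in treated, floored at zero — a simple incremental
definition that ignores replacement of leavers and therefore
underestimates initiation visits slightly.

On the literal reading of the published schedule the ramp value *at* 2025
is zero; reported treated counts in 2025 suggest the original analysis
used a nonzero first step. The schedule object makes the first-year value
configurable; the presets use 0 at 2025.

The four core presets are high uptake × {30 %, 25 %, 20 %} efficacy and
low uptake × 25 % efficacy, each available with either care model:
majority-primary (4 primary visits/year) or majority-specialist (2 primary
+ 2 specialist visits/year), both with one initiation specialist visit per
new starter. For identical trajectories the two care models differ by
exactly 2 × (£465 − £33) = £864 per treated person-year (initiation visits
cancel), which the tests assert as an algebraic identity. Follow-up visits
are charged in the initiation year on top of the initiation appointment;
this is the simpler convention and is configurable through the care-model
fields. Drug costs (`treated × annual price`) are disabled unless a price
is supplied, reflecting the absence of a UK price precedent.

Cost offsets are scenario minus baseline (negative = saving, the
convention of change-versus-baseline reporting tables); headline "savings"
figures flip the sign. Because treated people incur visit costs before
progression benefits accrue, the first post-launch year's offset is
non-negative — an invariant the tests check. The per-treated-patient
saving is reported under both available denominators (that year's treated
count, and cumulative treated person-years), since reported headline
figures do not disambiguate them.

## Synthetic data

`synthetic_population_projection()` emulates the *shape* of a national
projection, not its values: a smooth two-parameter age curve (Gaussian in
age, centre ≈ median age 41, dispersion 24) with a fixed multiplicative
band-level jitter (3 % lognormal, seeded), 50.7 % female share, geometric
total growth (0.4 %/year) and an upward drift of the age-structure centre
(0.15 years/year) producing a rising 65+ share. Defaults were chosen once
to resemble UK demography at the base year. What it does **not** emulate:
cohort bulges (baby boomers), migration waves, band-specific mortality
improvements, or the very steep thinning of the 95+ bands in real data —
its extreme-age cells are fatter than reality. Passing tests on synthetic
data therefore demonstrate the machinery (conservation, monotonicity,
directional scenario economics), not calibrated UK forecasts.

`random_model()` draws fully valid parameter bundles for property tests:
outflow-constrained transition draws (each state's outgoing edges scaled
onto a total in 0.4–0.8), renormalised severity rows, monotone incidence
built from cumulative sums, positive costs. Prevalence and incidence
ceilings are deliberately modest so that generated models stay in the
regime the residual identity assumes — disease occupancy well below the
projection — across the whole seed range the tests sweep.

## Numerical choices and degenerate inputs

* Everything is double-precision linear algebra on 5 × 21 × 2 arrays; no
  stochastic simulation, so projections are bitwise deterministic and the
  runner's CSV outputs are byte-identical across reruns.
* "Yearly rates" are treated as annual transition *probabilities* applied
  once per cycle (per-state outflow sums validated ≤ 1), not hazards to
  exponentiate — the convention of annual-cycle spreadsheet Markov models.
  No half-cycle correction is applied, matching that convention.
* If user-supplied rates push disease states above the projection in a
  cell, the residual is clamped to zero and a warning is recorded on the
  state vector and the trajectory (fail-soft with diagnostics);
  initialisation, where the same situation signals inconsistent prevalence
  inputs, fails hard naming the cell.
* Validation returns violations as data (field, rule, message) rather than
  exceptions, so a config can be audited in one pass; the runner refuses
  to start on any violation.
* Config round-trips use JSON at full numeric precision by default; YAML
  is accepted on input and written at 15 significant digits.

## Problem sizes in the test-suite

The property suites run on deliberately small problems — synthetic
populations of a few million people, 21 bands × 2 sexes × 21 years, 100
random parameter draws for conservation, smaller sweeps for monotonicity —
chosen so the full suite completes in well under a minute while still
exercising every code path at realistic array shapes.

## Known limitations

* No microsimulation: no individual heterogeneity, treatment duration
  rules, discontinuation, dosing or adverse-event states.
* Age-invariant disease mortality interacts badly with the open 100+ band
  under low-mortality/high-progression parameter combinations (occupancy
  can exceed the projection there); the clamping diagnostics make this
  visible rather than silent.
* Informal/unpaid care, out-of-pocket social care, diagnostic-capacity
  capital costs and inflation adjustment are out of scope.
* The placeholder transitions are not estimates. Any substantive result
  requires user-supplied transition probabilities; every output of the
  reference bundle should be read as a demonstration of the machinery.
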