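# adcohort

An age- and sex-stratified **cohort Markov model** of Alzheimer's disease
(AD) progression for projecting the health and social care costs of AD
dementia in the UK, and for exploring what disease-modifying therapies
(DMTs) could change. It is aimed at health-economics and health-system
planning analysts who need population-level scenario projections — not
individual-level microsimulation — of treatment efficacy, uptake, and
follow-up care models.

## The model

The population is stratified into 5-year age bands (0–4 … 100+) and sex,
and distributed across five mutually exclusive states:

```
unimpaired -> MCI due to AD -> mild AD -> moderate AD -> severe AD
                                  ^     <-    |    ^   <-   |
                                  (backward transitions)
```

Each calendar year (annual cycles, 2020–2040 by default):

1. **Transitions.** State occupancies flow along the allowed edges with
   fixed annual probabilities `p(s -> s')`: forward progression, two
   backward transitions (accounting for stage misclassification), and
   state-specific mortality. Transition probabilities are age-invariant
   except MCI incidence.
2. **Incidence.** The unimpaired population enters MCI due to AD with an
   age-specific annual probability that rises with age.
3. **Ageing.** Each band passes 1/5 of its survivors to the next band; the
   open 100+ band retains.
4. **Residual.** The unimpaired population is recomputed as the national
   population projection minus all disease states, so background mortality
   and migration are implicit in the projection.

Costs per projected year are

```
health = sum_cells [ non-AD persons x HCRU(band, sex) ]
       + sum_cells [ AD persons(stage) x AD-HCRU(band) x r_h(stage) ]
social = sum_cells [ non-AD persons x social_general(age) ]
       + sum_cells [ AD persons(stage) x social_AD(sex) x r_s(stage) x u ]
```

with stage cost ratios `r_h`, `r_s` relative to the all-severity AD cost
and social-care utilisation `u = 0.48`. DMT scenarios multiply the two
forward edges out of the treated states (MCI -> mild, mild -> moderate) by
`1 - efficacy x uptake(year)`, where uptake ramps linearly (e.g. 0 % to
58 % over 2025–2034), and add follow-up visit costs (£33 per primary care
visit, £465 per specialist visit) and optionally drug costs. Offsets are
scenario minus baseline totals (negative = saving). All amounts are 2019
GBP, undiscounted.

The packaged reference bundle (`reference_parameters()`) carries published
UK estimates for prevalence, MCI incidence, severity splits, cost ratios
and unit costs. **Transition probabilities between disease states are not
published in that set and ship as clearly flagged illustrative
placeholders** — supply your own estimates for substantive use. The default
population is a synthetic, UK-like projection
(`synthetic_population_projection()`), so everything runs with no external
data.

## Worked example

```r
library(adcohort)

params <- reference_parameters()       # published values + placeholders
baseline <- project(params)
baseline
#> <trajectory> baseline (no DMT), 2020-2040
#>   AD dementia: 582433 (2020) -> 985778 (2040)

sc   <- core_scenarios()$high_uptake_medium_efficacy
traj <- project(params, sc)
ts   <- treatment_series(traj, sc)
off  <- offsets(cost_series(baseline, params),
                cost_series(traj, params, treatment = ts), ts)

ts$treated[21]                 # 623262  people on DMT in 2040
off$cumulative_offset[21]/1e9  # -5.93   bn GBP vs baseline (negative = saving)
off$saving_per_treated[21]     # 1122    GBP saved per treated person-year in 2040
```

Read: under 25 % efficacy and 58 % uptake with majority-primary follow-up,
the model projects ~33,000 fewer AD dementia cases in 2040 and a £5.9 bn
cumulative saving over 2020–2040 against the no-DMT baseline — on the
*synthetic* population and *placeholder* transitions, so the magnitudes
illustrate the machinery rather than forecast the UK.

A command-line runner over the same functions writes trajectory, cost,
offset and summary files:

```sh
Rscript inst/scripts/adcohort-run.R --config my_params.json --out out/ --scenarios core4
```

## Package layout

- `R/` — parameter types, validation and config I/O; the cohort engine;
  DMT scenarios; the costing engine; the synthetic population generator;
  the runner/reporting layer.
- `vignettes/cohort-model.Rmd` — the model, its assumptions, parameter
  choices and limitations.
- `tests/testthat/` — unit and property tests, including an independent
  edge-by-edge flow-ledger oracle for the engine.
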