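Package: adcohort
Title: Cohort Markov Projection of Alzheimer's Disease Burden and Care Costs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An age- and sex-stratified cohort Markov model of progression
    through mild cognitive impairment (MCI) due to Alzheimer's disease (AD)
    and mild, moderate and severe AD dementia, projected against national
    population projections over annual cycles. Includes a scenario engine
    for disease-modifying therapy (DMT) efficacy, uptake ramps and follow-up
    care models, a costing engine for health, social-care, follow-up-visit
    and drug costs with cumulative offsets versus a no-treatment baseline,
    a synthetic population generator for fully self-contained runs, and a
    command-line style runner that writes trajectories, cost series and a
    summary grid.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
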