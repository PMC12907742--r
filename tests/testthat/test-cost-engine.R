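one_person_state <- function(state_name, band, sex) {
  cn <- array(0, dim = c(5, 21, 2))
  cn[match(state_name, c("unimpaired", "mci", "mild", "moderate", "severe")),
     match(band, band_labels()), match(sex, model_sexes())] <- 1
  state_vector(2020, cn)
}

test_that("state costs follow the severity-ratio scaling by hand arithmetic", {
  costs <- reference_parameters()$costs

  sev <- state_costs(one_person_state("severe", "80-84", "male"), costs)
  expect_equal(unname(sev[["health"]]), 4643.33 * 1.7597, tolerance = 1e-9)
  expect_equal(unname(sev[["health"]]), 8170.87, tolerance = 1e-2)
  expect_equal(unname(sev[["social"]]), 12526 * 1.7622 * 0.48,
               tolerance = 1e-9)
  expect_equal(unname(sev[["social"]]), 10594.87, tolerance = 1e-2)

  mild_f <- state_costs(one_person_state("mild", "70-74", "female"), costs)
  expect_equal(unname(mild_f[["health"]]), 4019.29 * 0.5548,
               tolerance = 1e-9)
  expect_equal(unname(mild_f[["social"]]), 12480 * 0.4261 * 0.48,
               tolerance = 1e-9)

  # people without AD dementia are costed at general-population rates
  u <- state_costs(one_person_state("unimpaired", "80-84", "male"), costs)
  expect_equal(unname(u[["health"]]), 4181.89, tolerance = 1e-9)
  expect_equal(unname(u[["social"]]), 499.89, tolerance = 1e-9)
  mci <- state_costs(one_person_state("mci", "40-44", "female"), costs)
  expect_equal(unname(mci[["health"]]), 1268.05, tolerance = 1e-9)
  expect_equal(unname(mci[["social"]]), 200.26, tolerance = 1e-9)
  child <- state_costs(one_person_state("unimpaired", "10-14", "male"),
                       costs)
  expect_equal(unname(child[["social"]]), 0)

  empty <- state_costs(state_vector(2020, array(0, dim = c(5, 21, 2))),
                       costs)
  expect_identical(unname(empty), c(0, 0))
})

test_that("follow-up visit costs match the care-model visit mixes", {
  costs <- reference_parameters()$costs
  series <- data.frame(year = 2030, eligible = 1000, uptake = 0.1,
                       treated = 100, new_starters = 0)
  expect_equal(followup_costs(series, care_model_primary(), costs),
               100 * 4 * 33)
  expect_equal(followup_costs(series, care_model_specialist(), costs),
               100 * (2 * 33 + 2 * 465))
  series$new_starters <- 20
  expect_equal(followup_costs(series, care_model_primary(), costs),
               13200 + 20 * 465)
  series$treated <- 0; series$new_starters <- 0
  expect_equal(followup_costs(series, care_model_primary(), costs), 0)
})

test_that("drug costs reproduce the published annual bounds at 1 d.p.", {
  series <- data.frame(year = 2040, eligible = 3.5e6, uptake = 0.58,
                       treated = 2018749, new_starters = 0)
  expect_equal(round(drug_costs(series, 1200) / 1e9, 1), 2.4)
  expect_equal(round(drug_costs(series, 21000) / 1e9, 1), 42.4)
  expect_identical(drug_costs(series, 0), 0)
})

test_that("cost series are additive, cumulative and currency-consistent", {
  params <- small_reference(seed = 10L)
  sc <- core_scenarios()$high_uptake_medium_efficacy
  traj <- project(params, sc)
  ts <- treatment_series(traj, sc)
  cs <- cost_series(traj, params, treatment = ts)

  expect_equal(cs$total, cs$health + cs$social + cs$followup + cs$drug,
               tolerance = 1e-9)
  expect_equal(cs$cumulative, cumsum(cs$total), tolerance = 1e-6)
  expect_true(all(cs[, c("health", "social", "followup", "drug")] >= 0))
  expect_identical(attr(cs, "currency"), "GBP 2019")
  # drug price absent: drug column identically zero
  expect_true(all(cs$drug == 0))

  # with a price configured the drug column is treated x price
  params2 <- params
  params2$costs$drug_price_annual <- 1200
  cs2 <- cost_series(traj, params2, treatment = ts)
  expect_equal(cs2$drug, ts$treated * 1200, tolerance = 1e-9)
})

test_that("care-model identity: specialist minus primary is 864 per treated person-year", {
  params <- small_reference(seed = 12L)
  sc_p <- scenario_spec("p", 0.25, uptake_schedule(2025L, 2034L, 0.58),
                        care_model_primary())
  sc_s <- scenario_spec("s", 0.25, uptake_schedule(2025L, 2034L, 0.58),
                        care_model_specialist())
  traj <- project(params, sc_p)  # identical trajectories either way
  ts <- treatment_series(traj, sc_p)
  cs_p <- cost_series(traj, params, treatment = ts,
                      care = care_model_primary())
  cs_s <- cost_series(traj, params, treatment = ts,
                      care = care_model_specialist())
  diff_total <- sum(cs_s$total) - sum(cs_p$total)
  expect_equal(diff_total, 864 * sum(ts$treated), tolerance = 1e-6)
})

test_that("offsets difference the totals with the documented sign convention", {
  mk_cs <- function(totals) {
    out <- data.frame(year = 2020:2022, health = totals, social = 0,
                      followup = 0, drug = 0, total = totals,
                      cumulative = cumsum(totals))
    class(out) <- c("cost_series", "data.frame")
    out
  }
  base <- mk_cs(c(100, 100, 100))
  scen <- mk_cs(c(110, 95, 80))
  ts <- data.frame(year = 2020:2022, eligible = 100, uptake = 1,
                   treated = c(0, 10, 10), new_starters = c(0, 10, 0))
  off <- offsets(base, scen, ts)
  expect_equal(off$offset, c(10, -5, -20))
  expect_equal(off$cumulative_offset, c(10, 5, -15))
  expect_true(is.na(off$saving_per_treated[1]))
  expect_equal(off$saving_per_treated[2:3], c(0.5, 2))
  expect_equal(off$saving_per_cumulative_treated[3], 15 / 20)

  expect_equal(offsets(base, base, ts)$offset, c(0, 0, 0))
  bad <- mk_cs(c(1, 2, 3)); bad$year <- 2021:2023
  expect_error(offsets(base, bad, ts), "different years")
})

test_that("dementia count changes versus baseline difference the trajectories", {
  b <- trajectory_from_counts(2020:2022, c(100, 110, 120))
  s <- trajectory_from_counts(2020:2022, c(100, 105, 112))
  ch <- change_vs_baseline(b, s)
  expect_equal(ch$change, c(0, -5, -8))
  expect_equal(change_vs_baseline(b, b)$change, c(0, 0, 0))
  s2 <- trajectory_from_counts(2021:2023, c(1, 2, 3))
  expect_error(change_vs_baseline(b, s2), "different years")
})

test_that("percent increase is the rounded relative growth", {
  expect_identical(percent_increase(570212, 1038405), 82)
  expect_identical(percent_increase(100, 150), 50)
  expect_identical(percent_increase(250, 250), 0)
  expect_error(percent_increase(0, 5), "non-positive")
})

test_that("first post-launch offset is non-negative before benefits accrue", {
  params <- small_reference(seed = 14L)
  baseline <- project(params)
  cs_b <- cost_series(baseline, params)
  sc <- core_scenarios()$high_uptake_medium_efficacy
  traj <- project(params, sc)
  ts <- treatment_series(traj, sc)
  cs <- cost_series(traj, params, treatment = ts)
  off <- offsets(cs_b, cs, ts)
  first_treated <- min(off$year[ts$treated > 0])
  expect_gte(off$offset[off$year == first_treated], 0)
  # pre-launch years: trajectories identical, offsets exactly zero
  expect_true(all(off$offset[off$year < sc$launch_year] == 0))
})
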