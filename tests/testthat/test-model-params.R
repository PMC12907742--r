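test_that("packaged reference bundle reproduces the published table cells", {
  params <- reference_parameters()

  # prevalence / incidence spot checks across the grid
  expect_identical(params$prev_ad["80-84", "male"], 0.0689)
  expect_identical(params$prev_ad["85-89", "female"], 0.1177)
  expect_identical(params$prev_ad["30-34", "male"], 0.0001)
  expect_identical(params$prev_ad["100+", "female"], 0.2275)
  expect_identical(unname(params$prev_mci[["90-94"]]), 0.2757)
  expect_identical(unname(params$prev_mci[["65-69"]]), 0.0416)
  expect_identical(unname(params$transitions$incidence[["100+"]]), 0.1990)
  expect_identical(unname(params$transitions$incidence[["80-84"]]), 0.0265)

  # bands below 30 carry no disease
  expect_true(all(params$prev_ad[1:6, ] == 0))
  expect_true(all(params$prev_mci[1:6] == 0))
  expect_true(all(params$transitions$incidence[1:6] == 0))

  # costs
  cp <- params$costs
  expect_identical(cp$england_hcru["30-34", "male"], 693.86)
  expect_identical(cp$england_hcru["100+", "female"], 2088.91)
  expect_identical(unname(cp$ad_hcru[["80-84"]]), 4643.33)
  expect_identical(unname(cp$health_ratios[["severe"]]), 1.7597)
  expect_identical(unname(cp$health_ratios[["mild"]]), 0.5548)
  expect_identical(unname(cp$social_ratios[["moderate"]]), 1.7049)
  expect_identical(unname(cp$social_ad[["male"]]), 12526)
  expect_identical(unname(cp$social_ad[["female"]]), 12480)
  expect_identical(cp$social_utilisation, 0.48)
  expect_identical(unname(cp$social_general[["adult"]]), 200.26)
  expect_identical(unname(cp$social_general[["senior"]]), 499.89)
  expect_identical(cp$primary_visit_cost, 33)
  expect_identical(cp$specialist_visit_cost, 465)

  # severity split rows as published
  sv <- params$severity
  expect_identical(sv$mild, c(0.5882, 0.1792, 0.1897, 0.1470))
  expect_identical(sv$moderate, c(0.3529, 0.4083, 0.4018, 0.3153))
  expect_identical(sv$severe, c(0.0588, 0.4125, 0.4084, 0.5378))

  # scenario presets
  sc <- core_scenarios()
  expect_identical(sc$high_uptake_high_efficacy$efficacy, 0.30)
  expect_identical(sc$high_uptake_medium_efficacy$efficacy, 0.25)
  expect_identical(sc$high_uptake_low_efficacy$efficacy, 0.20)
  expect_identical(sc$high_uptake_high_efficacy$uptake$max_uptake, 0.58)
  expect_identical(sc$low_uptake_medium_efficacy$uptake$max_uptake, 0.25)
  expect_identical(sc$high_uptake_high_efficacy$uptake$start_year, 2025L)
  expect_identical(sc$high_uptake_high_efficacy$uptake$ramp_end_year, 2034L)

  # drug price absent by default; provenance flags non-published groups
  expect_null(cp$drug_price_annual)
  expect_identical(unname(params$provenance[["transitions"]]), "placeholder")
})

test_that("the reference bundle validates cleanly and violations are data", {
  params <- reference_parameters()
  expect_identical(nrow(validate_parameters(params)), 0L)

  bad <- params
  bad$severity$mild[2] <- 0.5
  bad$severity$moderate[2] <- 0.5
  bad$severity$severe[2] <- 0.5
  v <- validate_parameters(bad)
  expect_identical(v$rule, "split_sums_to_one")
  expect_match(v$message, "1.5")

  bad2 <- params
  bad2$transitions$mild_moderate <- 0.95
  bad2$transitions$mort_mild <- 0.25
  v2 <- validate_parameters(bad2)
  expect_true("outflow_sum" %in% v2$rule)
  expect_match(v2$field[v2$rule == "outflow_sum"], "mild")
})

test_that("randomly perturbed-invalid bundles always raise a violation", {
  params <- small_reference()
  perturb <- list(
    function(p) { p$prev_ad[10, 1] <- 1.4; p },
    function(p) { p$prev_mci[12] <- -0.1; p },
    function(p) { p$transitions$mort_severe <- 1.2; p },
    function(p) { p$transitions$incidence[15] <- 0.001; p }, # breaks monotone
    function(p) { p$costs$primary_visit_cost <- -5; p },
    function(p) { p$costs$social_utilisation <- 1.3; p },
    function(p) { p$costs$health_ratios[["mild"]] <- 0; p },
    function(p) { p$severity$severe[4] <- 0.9; p },
    function(p) { dimnames(p$population)[[1]] <- as.character(2021:2041); p })
  for (f in perturb) {
    expect_gte(nrow(validate_parameters(f(params))), 1L)
  }
})

test_that("config files round-trip parameters exactly", {
  params <- small_reference(seed = 3L)
  path <- withr::local_tempfile(fileext = ".json")
  write_parameters(params, path)
  back <- load_parameters(path)

  expect_equal(back$population, params$population, tolerance = 1e-12)
  expect_equal(unclass(back$prev_ad), unclass(params$prev_ad),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$prev_mci, params$prev_mci, tolerance = 1e-12)
  expect_equal(back$transitions[1:9], params$transitions[1:9])
  expect_equal(back$transitions$incidence, params$transitions$incidence,
               tolerance = 1e-12)
  expect_equal(as.data.frame(unclass(back$severity)),
               as.data.frame(unclass(params$severity)), tolerance = 1e-12)
  expect_equal(back$costs$ad_hcru, params$costs$ad_hcru, tolerance = 1e-12)
  expect_equal(back$costs$social_ad, params$costs$social_ad)
  expect_identical(back$base_year, params$base_year)
  expect_identical(back$currency, params$currency)
  expect_identical(nrow(validate_parameters(back)), 0L)

  # YAML dialect loads too
  ypath <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(params, ypath)
  yback <- load_parameters(ypath)
  expect_equal(yback$population, params$population, tolerance = 1e-9)
})

test_that("config loading errors name the missing piece", {
  params <- small_reference()
  path <- withr::local_tempfile(fileext = ".json")
  write_parameters(params, path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)

  cfg_bad <- cfg; cfg_bad$costs <- NULL
  p1 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg_bad, p1, auto_unbox = TRUE, digits = NA)
  expect_error(load_parameters(p1), "costs")

  cfg_gap <- cfg
  keep <- cfg_gap$population$age_band != "100+"
  cfg_gap$population <- lapply(cfg_gap$population, function(col) col[keep])
  p2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg_gap, p2, auto_unbox = TRUE, digits = NA)
  expect_error(load_parameters(p2), "100\\+")

  expect_error(load_parameters("no/such/file.json"), "not found")
})

test_that("tabular CSV dialects round-trip with the 100+ band spelled out", {
  params <- small_reference(seed = 5L)
  pp <- withr::local_tempfile(fileext = ".csv")
  write_population_csv(params$population, pp)
  raw <- utils::read.csv(pp)
  expect_true(all(c("year", "age_band", "sex", "value") %in% names(raw)))
  expect_true("100+" %in% raw$age_band)
  expect_equal(read_population_csv(pp), params$population,
               tolerance = 1e-12)

  sp <- withr::local_tempfile(fileext = ".csv")
  write_stratified_csv(params$prev_ad, sp)
  back <- read_stratified_csv(sp, units = "probability")
  expect_equal(unclass(back), unclass(params$prev_ad), tolerance = 1e-12,
               ignore_attr = TRUE)
})
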