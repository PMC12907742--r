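# Config file round-trip: one structured JSON or YAML file with sections
# population, prevalence, incidence, transitions, severity, costs and
# (optionally) scenario_defaults. JSON is the default dialect because it
# round-trips doubles at full precision.

params_to_config <- function(params) {
  pop <- params$population
  yrs <- dimnames(pop)[[1]]
  long <- expand.grid(year = as.integer(yrs), age_band = band_labels(),
                      sex = model_sexes(), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  long$value <- as.vector(pop)
  cp <- params$costs
  cfg <- list(
    base_year = params$base_year,
    horizon_year = params$horizon_year,
    currency = params$currency,
    population = as.list(long),
    prevalence = list(
      age_band = band_labels(),
      ad_male = unname(params$prev_ad[, "male"]),
      ad_female = unname(params$prev_ad[, "female"]),
      mci = unname(params$prev_mci)
    ),
    incidence = list(age_band = band_labels(),
                     mci = unname(params$transitions$incidence)),
    transitions = params$transitions[setdiff(names(params$transitions),
                                             "incidence")],
    severity = as.list(as.data.frame(unclass(params$severity))),
    costs = list(
      england_hcru = list(age_band = band_labels(),
                          male = unname(cp$england_hcru[, "male"]),
                          female = unname(cp$england_hcru[, "female"])),
      ad_hcru = list(age_band = band_labels(), value = unname(cp$ad_hcru)),
      social_general = as.list(cp$social_general),
      social_ad = as.list(cp$social_ad),
      social_utilisation = cp$social_utilisation,
      health_ratios = as.list(cp$health_ratios),
      social_ratios = as.list(cp$social_ratios),
      primary_visit_cost = cp$primary_visit_cost,
      specialist_visit_cost = cp$specialist_visit_cost
    ),
    provenance = as.list(params$provenance)
  )
  if (!is.null(cp$drug_price_annual))
    cfg$costs$drug_price_annual <- cp$drug_price_annual
  cfg
}

#' Write a model parameter bundle to a config file
#'
#' @param params A [model_parameters()] object.
#' @param path Output path; `.json` (default dialect, full numeric
#'   precision) or `.yaml`/`.yml`.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  cfg <- params_to_config(params)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(cfg, path, precision = 15L)
  } else {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

config_field <- function(cfg, name) {
  if (is.null(cfg[[name]]))
    stop(sprintf("config schema error: required section '%s' is missing",
                 name), call. = FALSE)
  cfg[[name]]
}

check_band_coverage <- function(labels, where) {
  missing <- setdiff(band_labels(), labels)
  if (length(missing))
    stop(sprintf("config validation error: %s does not cover age band(s) %s",
                 where, paste(missing, collapse = ", ")), call. = FALSE)
}

# reorder a vector supplied alongside an age_band column into canonical order
by_band <- function(section, col, where) {
  check_band_coverage(section$age_band, where)
  as.numeric(section[[col]])[match(band_labels(), section$age_band)]
}

#' Load and validate a model parameter bundle from a config file
#'
#' Reads the structured config (JSON or YAML), checks the schema (a missing
#' required section is an error naming the section; an age-band coverage gap
#' is an error naming the band), and returns a fully populated
#' [model_parameters()] object. Optional fields take documented defaults:
#' `currency` defaults to `"GBP 2019"` and `drug_price_annual` is absent
#' unless supplied (disabling drug-cost outputs). The returned object's
#' `provenance` field records, per parameter group, whether values come from
#' published estimates, are illustrative placeholders, or are synthetic.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` config file.
#' @return A [model_parameters()] object.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  for (sec in c("population", "prevalence", "incidence", "transitions",
                "severity", "costs", "base_year", "horizon_year"))
    config_field(cfg, sec)

  popl <- as.data.frame(cfg$population, stringsAsFactors = FALSE)
  for (col in c("year", "age_band", "sex", "value"))
    if (is.null(popl[[col]]))
      stop(sprintf("config schema error: population lacks column '%s'", col),
           call. = FALSE)
  check_band_coverage(unique(popl$age_band), "population")
  yrs <- sort(unique(as.integer(popl$year)))
  pop <- array(NA_real_, dim = c(length(yrs), n_bands(), 2L),
               dimnames = list(year = yrs, band = band_labels(),
                               sex = model_sexes()))
  pop[cbind(match(popl$year, yrs), match(popl$age_band, band_labels()),
            match(popl$sex, model_sexes()))] <- popl$value
  if (anyNA(pop))
    stop("config validation error: population table has missing (year, age_band, sex) cells",
         call. = FALSE)

  prev <- cfg$prevalence
  prev_ad <- stratified_table(cbind(
    male = by_band(prev, "ad_male", "prevalence"),
    female = by_band(prev, "ad_female", "prevalence")), "probability")
  prev_mci <- by_band(prev, "mci", "prevalence")

  trs <- cfg$transitions
  tr <- transition_rates(
    mci_mild = trs$mci_mild, mild_moderate = trs$mild_moderate,
    moderate_severe = trs$moderate_severe, moderate_mild = trs$moderate_mild,
    severe_moderate = trs$severe_moderate,
    mort_mci = trs$mort_mci, mort_mild = trs$mort_mild,
    mort_moderate = trs$mort_moderate, mort_severe = trs$mort_severe,
    incidence = by_band(cfg$incidence, "mci", "incidence"))

  sv <- cfg$severity
  split <- severity_split(sv$group_lower, sv$mild, sv$moderate, sv$severe)

  cc <- cfg$costs
  costs <- cost_parameters(
    england_hcru = stratified_table(cbind(
      male = by_band(cc$england_hcru, "male", "costs$england_hcru"),
      female = by_band(cc$england_hcru, "female", "costs$england_hcru")),
      "gbp_per_person_year"),
    ad_hcru = by_band(cc$ad_hcru, "value", "costs$ad_hcru"),
    social_general = unlist(cc$social_general),
    social_ad = unlist(cc$social_ad),
    social_utilisation = cc$social_utilisation,
    health_ratios = unlist(cc$health_ratios),
    social_ratios = unlist(cc$social_ratios),
    primary_visit_cost = cc$primary_visit_cost,
    specialist_visit_cost = cc$specialist_visit_cost,
    drug_price_annual = cc$drug_price_annual)

  params <- model_parameters(
    population = pop, prev_ad = prev_ad, prev_mci = prev_mci,
    severity = split, transitions = tr, costs = costs,
    base_year = cfg$base_year, horizon_year = cfg$horizon_year,
    currency = if (is.null(cfg$currency)) "GBP 2019" else cfg$currency,
    provenance = unlist(cfg$provenance))
  params
}

# ---- tabular CSV import/export -------------------------------------------

#' Read and write the tabular CSV dialects
#'
#' Population tables use columns `year, age_band, sex, value`; stratified
#' tables use `age_band, sex, value`. Band labels are spelled `0-4` ...
#' `95-99`, `100+`; files are UTF-8.
#'
#' @param pop A population array `[year, band, sex]`.
#' @param table A [stratified_table()].
#' @param path CSV path.
#' @param units Units tag for the re-imported stratified table.
#' @return The written path (writers, invisibly); a population array or
#'   `stratified_table` (readers).
#' @name csv_io
NULL

#' @rdname csv_io
#' @export
write_population_csv <- function(pop, path) {
  yrs <- dimnames(pop)[[1]]
  long <- expand.grid(year = as.integer(yrs), age_band = band_labels(),
                      sex = model_sexes(), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  long$value <- as.vector(pop)
  long <- long[order(long$year, match(long$age_band, band_labels()),
                     long$sex), ]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname csv_io
#' @export
read_population_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  check_band_coverage(unique(long$age_band), "population CSV")
  yrs <- sort(unique(long$year))
  pop <- array(NA_real_, dim = c(length(yrs), n_bands(), 2L),
               dimnames = list(year = yrs, band = band_labels(),
                               sex = model_sexes()))
  pop[cbind(match(long$year, yrs), match(long$age_band, band_labels()),
            match(long$sex, model_sexes()))] <- long$value
  pop
}

#' @rdname csv_io
#' @export
write_stratified_csv <- function(table, path) {
  long <- expand.grid(age_band = band_labels(), sex = model_sexes(),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  long$value <- as.vector(table)
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname csv_io
#' @export
read_stratified_csv <- function(path, units = "probability") {
  long <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  check_band_coverage(unique(long$age_band), "stratified CSV")
  m <- matrix(NA_real_, n_bands(), 2L)
  m[cbind(match(long$age_band, band_labels()),
          match(long$sex, model_sexes()))] <- long$value
  stratified_table(m, units)
}
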