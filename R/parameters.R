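#' Build a stratified (age band x sex) parameter table
#'
#' A thin wrapper around a numeric matrix with one row per 5-year age band
#' and one column per sex, carrying a units tag so that probabilities and
#' monetary values are not silently mixed.
#'
#' @param values Numeric matrix (21 x 2), or a single vector recycled to both
#'   sexes, ordered as [age_bands()].
#' @param units One of `"probability"`, `"gbp_per_person_year"`,
#'   `"proportion"`, `"persons"`.
#' @return A `stratified_table`: numeric matrix with dimnames
#'   (band label, sex) and a `units` attribute.
#' @export
stratified_table <- function(values, units = c("probability",
                                               "gbp_per_person_year",
                                               "proportion", "persons")) {
  units <- match.arg(units)
  if (is.vector(values)) values <- cbind(male = values, female = values)
  values <- as.matrix(values)
  stopifnot(nrow(values) == n_bands(), ncol(values) == 2L)
  dimnames(values) <- list(band = band_labels(), sex = model_sexes())
  structure(values, units = units, class = c("stratified_table", "matrix"))
}

#' Annual transition probabilities between disease states
#'
#' The allowed edges are forward progression (MCI due to AD -> mild ->
#' moderate -> severe AD dementia), two backward edges accounting for stage
#' misclassification (moderate -> mild, severe -> moderate), state-specific
#' mortality from each of the four disease states, and the age-specific
#' incidence of MCI due to AD out of the cognitively unimpaired population.
#' All values are annual probabilities applied once per cycle; rates are
#' identical across age bands except MCI incidence.
#'
#' @param mci_mild,mild_moderate,moderate_severe Forward progression
#'   probabilities.
#' @param moderate_mild,severe_moderate Backward transition probabilities.
#' @param mort_mci,mort_mild,mort_moderate,mort_severe Annual mortality
#'   probabilities from each disease state.
#' @param incidence Numeric vector of length 21: annual probability of
#'   unimpaired -> MCI by age band (non-decreasing with age).
#' @return A `transition_rates` list.
#' @export
transition_rates <- function(mci_mild, mild_moderate, moderate_severe,
                             moderate_mild, severe_moderate,
                             mort_mci, mort_mild, mort_moderate, mort_severe,
                             incidence) {
  incidence <- as.numeric(incidence)
  stopifnot(length(incidence) == n_bands())
  names(incidence) <- band_labels()
  structure(list(
    mci_mild = mci_mild, mild_moderate = mild_moderate,
    moderate_severe = moderate_severe, moderate_mild = moderate_mild,
    severe_moderate = severe_moderate,
    mort_mci = mort_mci, mort_mild = mort_mild,
    mort_moderate = mort_moderate, mort_severe = mort_severe,
    incidence = incidence
  ), class = "transition_rates")
}

#' Severity split of prevalent AD dementia by coarse age group
#'
#' @param groups_lower Integer lower bounds of the coarse age groups
#'   (e.g. `c(35, 65, 75, 85)`).
#' @param mild,moderate,severe Proportions per group; each row must sum to 1.
#' @return A `severity_split` data.frame.
#' @export
severity_split <- function(groups_lower, mild, moderate, severe) {
  structure(data.frame(group_lower = as.integer(groups_lower),
                       mild = mild, moderate = moderate, severe = severe),
            class = c("severity_split", "data.frame"))
}

# expand a severity_split to a 21 x 3 matrix by band containment
expand_severity_split <- function(split) {
  idx <- severity_group_for_band(split$group_lower)
  m <- as.matrix(split[idx, c("mild", "moderate", "severe")])
  dimnames(m) <- list(band = band_labels(),
                      severity = c("mild", "moderate", "severe"))
  m
}

#' Cost parameters for the health and social care costing engine
#'
#' @param england_hcru Stratified table: all-England per-person-per-year
#'   healthcare resource utilisation cost (GBP), applied to people without
#'   AD dementia (including MCI due to AD).
#' @param ad_hcru Numeric vector (21): all-severity AD dementia
#'   per-person-per-year healthcare cost by band (GBP; identical for both
#'   sexes, so stored once per band).
#' @param social_general Named vector `c(under18=, adult=, senior=)`:
#'   general-population formal social care cost per person-year (GBP),
#'   switching at ages 18 and 65.
#' @param social_ad Named vector `c(male=, female=)`: all-severity AD
#'   dementia formal social care cost per person-year (GBP).
#' @param social_utilisation Proportion of the AD dementia population using
#'   formal social care (applied to AD social costs only).
#' @param health_ratios,social_ratios Named vectors
#'   `c(mild=, moderate=, severe=)`: ratios of stage-specific cost to the
#'   all-severity AD dementia cost.
#' @param primary_visit_cost,specialist_visit_cost GBP per follow-up visit.
#' @param drug_price_annual Annual DMT price per treated person (GBP), or
#'   `NULL` to disable drug-cost outputs.
#' @return A `cost_parameters` list.
#' @export
cost_parameters <- function(england_hcru, ad_hcru, social_general, social_ad,
                            social_utilisation, health_ratios, social_ratios,
                            primary_visit_cost, specialist_visit_cost,
                            drug_price_annual = NULL) {
  ad_hcru <- as.numeric(ad_hcru)
  stopifnot(length(ad_hcru) == n_bands())
  names(ad_hcru) <- band_labels()
  structure(list(
    england_hcru = england_hcru, ad_hcru = ad_hcru,
    social_general = social_general, social_ad = social_ad,
    social_utilisation = social_utilisation,
    health_ratios = health_ratios, social_ratios = social_ratios,
    primary_visit_cost = primary_visit_cost,
    specialist_visit_cost = specialist_visit_cost,
    drug_price_annual = drug_price_annual
  ), class = "cost_parameters")
}

#' Assemble the full model parameter bundle
#'
#' @param population 3-d array `[year, band, sex]` of projected persons,
#'   with year dimnames covering `base_year:horizon_year`.
#' @param prev_ad Stratified table: baseline AD dementia prevalence by band
#'   and sex.
#' @param prev_mci Numeric vector (21): baseline prevalence of MCI due to AD
#'   (no sex split; applied to both sexes).
#' @param severity A [severity_split()].
#' @param transitions A [transition_rates()].
#' @param costs A [cost_parameters()].
#' @param base_year,horizon_year Calendar years of the projection window.
#' @param currency Currency label, default `"GBP 2019"`.
#' @param provenance Named character vector tagging parameter groups as
#'   `"published"`, `"placeholder"` or `"synthetic"`.
#' @return A `model_parameters` object.
#' @export
model_parameters <- function(population, prev_ad, prev_mci, severity,
                             transitions, costs,
                             base_year = 2020L, horizon_year = 2040L,
                             currency = "GBP 2019",
                             provenance = character()) {
  prev_mci <- as.numeric(prev_mci)
  stopifnot(length(prev_mci) == n_bands())
  names(prev_mci) <- band_labels()
  obj <- structure(list(
    population = population, prev_ad = prev_ad, prev_mci = prev_mci,
    severity = severity, transitions = transitions, costs = costs,
    base_year = as.integer(base_year),
    horizon_year = as.integer(horizon_year),
    currency = currency, provenance = provenance
  ), class = "model_parameters")
  obj
}

#' @export
print.model_parameters <- function(x, ...) {
  yrs <- dimnames(x$population)[[1]]
  cat("<model_parameters>\n")
  cat("  projection:", yrs[1], "-", yrs[length(yrs)],
      sprintf("(%d bands x 2 sexes)", n_bands()), "\n")
  cat("  window:", x$base_year, "-", x$horizon_year, " currency:",
      x$currency, "\n")
  if (length(x$provenance)) {
    plc <- names(x$provenance)[x$provenance != "published"]
    if (length(plc))
      cat("  non-published inputs:", paste(plc, collapse = ", "), "\n")
  }
  invisible(x)
}

population_years <- function(params) {
  as.integer(dimnames(params$population)[[1]])
}

# ---- validation -----------------------------------------------------------

violation <- function(field, rule, message) {
  data.frame(field = field, rule = rule, message = message,
             stringsAsFactors = FALSE)
}

no_violations <- function() {
  data.frame(field = character(), rule = character(), message = character(),
             stringsAsFactors = FALSE)
}

#' Validate a model parameter bundle
#'
#' Checks every structural invariant of the parameter bundle and returns the
#' violations as data rather than raising conditions, so a configuration can
#' be audited in one pass. An empty data.frame means the bundle is valid.
#'
#' Rules checked: probabilities in \[0, 1\]; for each disease state the sum of
#' outgoing transition probabilities (including mortality) at most 1; MCI
#' incidence non-decreasing with age; severity-split rows summing to 1
#' (tolerance 5e-4, admitting splits published as two-decimal percentages)
#' with all entries in \[0, 1\]; all monetary values and
#' cost ratios non-negative (ratios strictly positive); social-care
#' utilisation in \[0, 1\]; the population projection covering the model
#' window with non-negative counts.
#'
#' @param params A [model_parameters()] object.
#' @return A data.frame with columns `field`, `rule`, `message`; zero rows
#'   if and only if all invariants hold.
#' @export
validate_parameters <- function(params) {
  v <- list(no_violations())
  tr <- params$transitions

  prob_edges <- c("mci_mild", "mild_moderate", "moderate_severe",
                  "moderate_mild", "severe_moderate",
                  "mort_mci", "mort_mild", "mort_moderate", "mort_severe")
  for (e in prob_edges) {
    p <- tr[[e]]
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
      v <- c(v, list(violation(paste0("transitions$", e), "probability",
                               sprintf("value %s not in [0, 1]",
                                       format(p)))))
  }
  outflow <- list(
    mci = tr$mci_mild + tr$mort_mci,
    mild = tr$mild_moderate + tr$mort_mild,
    moderate = tr$moderate_severe + tr$moderate_mild + tr$mort_moderate,
    severe = tr$severe_moderate + tr$mort_severe
  )
  for (s in names(outflow)) {
    if (is.finite(outflow[[s]]) && outflow[[s]] > 1 + 1e-12)
      v <- c(v, list(violation(paste0("transitions[", s, "]"), "outflow_sum",
                               sprintf("outgoing probabilities sum to %.6g > 1",
                                       outflow[[s]]))))
  }
  inc <- tr$incidence
  if (any(inc < 0 | inc > 1, na.rm = TRUE))
    v <- c(v, list(violation("transitions$incidence", "probability",
                             "incidence outside [0, 1]")))
  if (any(diff(inc) < -1e-12, na.rm = TRUE))
    v <- c(v, list(violation("transitions$incidence", "monotone_incidence",
                             "MCI incidence must be non-decreasing with age")))

  for (nm in c("prev_ad", "prev_mci")) {
    p <- params[[nm]]
    if (any(p < 0 | p > 1, na.rm = TRUE))
      v <- c(v, list(violation(nm, "probability",
                               "prevalence outside [0, 1]")))
  }

  sp <- params$severity
  rows <- as.matrix(sp[, c("mild", "moderate", "severe")])
  # tolerance admits rows published as two-decimal percentages (99.99-100.01%)
  bad_sum <- abs(rowSums(rows) - 1) > 5e-4
  for (i in which(bad_sum))
    v <- c(v, list(violation(sprintf("severity[%d+]", sp$group_lower[i]),
                             "split_sums_to_one",
                             sprintf("severity proportions sum to %.6g",
                                     sum(rows[i, ])))))
  if (any(rows < 0 | rows > 1))
    v <- c(v, list(violation("severity", "proportion",
                             "severity proportions outside [0, 1]")))

  cp <- params$costs
  money <- c(cp$england_hcru, cp$ad_hcru, cp$social_general, cp$social_ad,
             cp$primary_visit_cost, cp$specialist_visit_cost,
             cp$drug_price_annual)
  if (any(money < 0, na.rm = TRUE))
    v <- c(v, list(violation("costs", "nonnegative_money",
                             "monetary values must be >= 0")))
  if (any(c(cp$health_ratios, cp$social_ratios) <= 0))
    v <- c(v, list(violation("costs$ratios", "positive_ratio",
                             "severity cost ratios must be > 0")))
  if (cp$social_utilisation < 0 || cp$social_utilisation > 1)
    v <- c(v, list(violation("costs$social_utilisation", "proportion",
                             "social care utilisation not in [0, 1]")))

  yrs <- population_years(params)
  need <- params$base_year:params$horizon_year
  if (!all(need %in% yrs))
    v <- c(v, list(violation("population", "coverage",
                             sprintf("projection missing years %s",
                                     paste(setdiff(need, yrs),
                                           collapse = ", ")))))
  if (any(params$population < 0, na.rm = TRUE))
    v <- c(v, list(violation("population", "nonnegative",
                             "population counts must be >= 0")))

  do.call(rbind, v)
}
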