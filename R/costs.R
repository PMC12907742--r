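# general-population social-care band rates: £0 under 18, the adult rate to
# 64, the senior rate from 65 (the 15-19 band straddles 18 and takes the
# adult rate)
social_general_by_band <- function(social_general) {
  ab <- age_bands()
  rate <- ifelse(ab$upper < 18, social_general[["under18"]],
                 ifelse(ab$lower >= 65, social_general[["senior"]],
                        social_general[["adult"]]))
  stats::setNames(rate, ab$label)
}

#' Annual health and social care cost of one state vector
#'
#' People without AD dementia (the unimpaired and MCI-due-to-AD states) are
#' costed at general-population rates: the all-England HCRU cost per person
#' per year by band and sex, and the general social-care cost switching at
#' ages 18 and 65. People in the AD dementia states are costed at the
#' all-severity AD rates scaled by the stage-specific cost ratios; AD
#' social-care costs are additionally multiplied by the formal social-care
#' utilisation proportion.
#'
#' @param state A [state_vector()].
#' @param costs A [cost_parameters()].
#' @return Named numeric `c(health =, social =)` in GBP per year.
#' @export
state_costs <- function(state, costs) {
  cn <- state$counts
  nonad <- cn["unimpaired", , ] + cn["mci", , ]

  health <- sum(nonad * costs$england_hcru)
  sg <- social_general_by_band(costs$social_general)
  social <- sum(nonad * sg)

  sev_names <- dementia_states()
  ad_social_rate <- matrix(costs$social_ad, n_bands(), 2L, byrow = TRUE)
  for (k in seq_along(sev_names)) {
    persons <- cn[sev_names[k], , ]
    health <- health + sum(persons * costs$ad_hcru *
                             costs$health_ratios[[k]])
    social <- social + sum(persons * ad_social_rate *
                             costs$social_ratios[[k]] *
                             costs$social_utilisation)
  }
  c(health = health, social = social)
}

#' Annual DMT follow-up visit costs
#'
#' Each treated person incurs the care model's annual follow-up visit mix;
#' each new starter additionally incurs the initiation specialist
#' appointment(s).
#'
#' @param series A [treatment_series()] data.frame.
#' @param care A [care_model()].
#' @param costs A [cost_parameters()] (visit unit costs).
#' @return Numeric vector of GBP per year, aligned with `series$year`.
#' @export
followup_costs <- function(series, care, costs) {
  per_treated <- care$primary_visits_per_year * costs$primary_visit_cost +
    care$specialist_visits_per_year * costs$specialist_visit_cost
  series$treated * per_treated +
    series$new_starters * care$initiation_specialist_visits *
      costs$specialist_visit_cost
}

#' Annual DMT drug costs
#'
#' @param series A [treatment_series()] data.frame.
#' @param annual_price Annual DMT price per treated person (GBP).
#' @return Numeric vector of GBP per year: `treated * annual_price`.
#' @export
drug_costs <- function(series, annual_price) {
  stopifnot(annual_price >= 0)
  series$treated * annual_price
}

#' Annual and cumulative cost series for a trajectory
#'
#' Health and social care costs come from [state_costs()] on every yearly
#' state vector. When a treatment series and care model are supplied,
#' follow-up visit costs are added; drug costs are added only when the
#' parameter bundle carries an annual drug price (otherwise the drug column
#' is zero throughout).
#'
#' @param traj A trajectory from [project()].
#' @param params A [model_parameters()].
#' @param treatment Optional [treatment_series()] data.frame.
#' @param care Optional [care_model()]; defaults to the trajectory
#'   scenario's care model when present.
#' @return A `cost_series` data.frame with columns `year`, `health`,
#'   `social`, `followup`, `drug`, `total`, `cumulative` (GBP), and a
#'   `currency` attribute.
#' @export
cost_series <- function(traj, params, treatment = NULL, care = NULL) {
  if (is.null(care) && !is.null(traj$scenario)) care <- traj$scenario$care_model
  if (is.null(treatment) && !is.null(traj$scenario))
    treatment <- treatment_series(traj, traj$scenario)

  hs <- t(vapply(traj$states, state_costs, numeric(2), costs = params$costs))
  followup <- rep(0, length(traj$years))
  drug <- rep(0, length(traj$years))
  if (!is.null(treatment)) {
    if (!identical(as.integer(treatment$year), as.integer(traj$years)))
      stop("treatment series years do not match the trajectory")
    if (!is.null(care))
      followup <- followup_costs(treatment, care, params$costs)
    if (!is.null(params$costs$drug_price_annual))
      drug <- drug_costs(treatment, params$costs$drug_price_annual)
  }
  total <- hs[, "health"] + hs[, "social"] + followup + drug
  out <- data.frame(year = traj$years, health = hs[, "health"],
                    social = hs[, "social"], followup = followup,
                    drug = drug, total = total,
                    cumulative = cumsum(total), row.names = NULL)
  attr(out, "currency") <- params$currency
  class(out) <- c("cost_series", "data.frame")
  out
}

#' Cost offsets of a scenario versus the no-treatment baseline
#'
#' The annual offset is scenario total minus baseline total, so a negative
#' value is a saving. Two per-treated-patient views are given: the annual
#' saving per person treated that year, and the cumulative saving per
#' cumulative treated person-year (both reported as positive savings).
#'
#' @param baseline,scenario `cost_series` for the same years.
#' @param series A [treatment_series()] data.frame for the scenario.
#' @return An `offset_series` data.frame with columns `year`, `offset`,
#'   `cumulative_offset`, `saving_per_treated` (NA where no one is
#'   treated), `saving_per_cumulative_treated`.
#' @export
offsets <- function(baseline, scenario, series) {
  if (!identical(as.integer(baseline$year), as.integer(scenario$year)))
    stop("baseline and scenario cost series cover different years")
  if (!identical(as.integer(series$year), as.integer(scenario$year)))
    stop("treatment series years do not match the cost series")
  offset <- scenario$total - baseline$total
  cum <- cumsum(offset)
  cum_treated <- cumsum(series$treated)
  out <- data.frame(
    year = baseline$year, offset = offset, cumulative_offset = cum,
    saving_per_treated = ifelse(series$treated > 0,
                                -offset / series$treated, NA_real_),
    saving_per_cumulative_treated = ifelse(cum_treated > 0,
                                           -cum / cum_treated, NA_real_),
    row.names = NULL)
  class(out) <- c("offset_series", "data.frame")
  out
}

#' Change in AD dementia counts versus baseline
#'
#' Per year, the total mild + moderate + severe AD dementia count under the
#' scenario minus the same total under the baseline (negative values mean
#' fewer cases under treatment).
#'
#' @param baseline,scenario Trajectories covering the same years.
#' @return A data.frame with columns `year`, `baseline`, `scenario`,
#'   `change`.
#' @export
change_vs_baseline <- function(baseline, scenario) {
  if (!identical(as.integer(baseline$years), as.integer(scenario$years)))
    stop("trajectories cover different years")
  b <- dementia_series(baseline)
  s <- dementia_series(scenario)
  data.frame(year = baseline$years, baseline = unname(b),
             scenario = unname(s), change = unname(s - b),
             row.names = NULL)
}

#' Build a minimal trajectory carrying given AD dementia totals
#'
#' Utility for summary-grid style inputs: constructs a trajectory whose
#' yearly AD dementia totals equal `counts` (all persons placed in the mild
#' state of one band), so count-difference operations such as
#' [change_vs_baseline()] can run on externally reported series. Years need
#' not be consecutive.
#'
#' @param years Calendar years.
#' @param counts AD dementia totals per year.
#' @return A trajectory-shaped object.
#' @export
trajectory_from_counts <- function(years, counts) {
  stopifnot(length(years) == length(counts))
  states <- lapply(seq_along(years), function(i) {
    cn <- array(0, dim = c(5L, n_bands(), 2L))
    cn[3L, n_bands(), 1L] <- counts[i]
    state_vector(years[i], cn)
  })
  names(states) <- years
  structure(list(years = as.integer(years), states = states,
                 diagnostics = NULL, warnings = character(),
                 scenario = NULL),
            class = "trajectory")
}

#' Percentage increase between two counts
#'
#' @param earlier,later Counts; `earlier` must be positive.
#' @return `100 * (later - earlier) / earlier`, rounded to the nearest
#'   integer percent (the reporting convention for headline prevalence
#'   growth).
#' @export
#' @examples
#' percent_increase(570212, 1038405)  # 82
percent_increase <- function(earlier, later) {
  if (!is.numeric(earlier) || earlier <= 0)
    stop("percent_increase is undefined for a non-positive earlier count")
  round(100 * (later - earlier) / earlier)
}
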