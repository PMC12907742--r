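#' Uptake schedule: linear ramp of the treated fraction
#'
#' Uptake is the fraction of the treatment-eligible population (MCI due to
#' AD plus mild AD dementia) receiving DMT in a given year: 0 before
#' `start_year`, rising linearly from 0 at `start_year` to `max_uptake` at
#' `ramp_end_year`, then constant.
#'
#' @param start_year First year of the ramp (uptake 0 at this year).
#' @param ramp_end_year Year the ramp reaches `max_uptake`.
#' @param max_uptake Plateau uptake proportion in \[0, 1\].
#' @return An `uptake_schedule` object.
#' @export
uptake_schedule <- function(start_year, ramp_end_year, max_uptake) {
  stopifnot(start_year < ramp_end_year, max_uptake >= 0, max_uptake <= 1)
  structure(list(start_year = as.integer(start_year),
                 ramp_end_year = as.integer(ramp_end_year),
                 max_uptake = max_uptake),
            class = "uptake_schedule")
}

#' @rdname uptake_schedule
#' @param schedule An `uptake_schedule`.
#' @param year Calendar year(s).
#' @return `uptake_at()`: the uptake proportion at `year` (vectorised).
#' @export
uptake_at <- function(schedule, year) {
  frac <- (year - schedule$start_year) /
    (schedule$ramp_end_year - schedule$start_year)
  schedule$max_uptake * pmin(pmax(frac, 0), 1)
}

#' Follow-up care models for DMT delivery
#'
#' Both care models start treatment with an initial specialist appointment;
#' they differ in the annual follow-up visit mix. The majority-primary model
#' uses 4 primary care follow-up visits per year; the majority-specialist
#' model uses 2 primary care and 2 specialist care follow-up visits per
#' year.
#'
#' @param label Care model name.
#' @param primary_visits_per_year,specialist_visits_per_year Annual
#'   follow-up visit counts per treated person.
#' @param initiation_specialist_visits Specialist visits per new starter.
#' @return A `care_model` object.
#' @export
care_model <- function(label, primary_visits_per_year,
                       specialist_visits_per_year,
                       initiation_specialist_visits = 1) {
  stopifnot(primary_visits_per_year >= 0, specialist_visits_per_year >= 0,
            initiation_specialist_visits >= 0)
  structure(list(label = label,
                 primary_visits_per_year = primary_visits_per_year,
                 specialist_visits_per_year = specialist_visits_per_year,
                 initiation_specialist_visits = initiation_specialist_visits),
            class = "care_model")
}

#' @rdname care_model
#' @export
care_model_primary <- function() {
  care_model("majority-primary", primary_visits_per_year = 4,
             specialist_visits_per_year = 0,
             initiation_specialist_visits = 1)
}

#' @rdname care_model
#' @export
care_model_specialist <- function() {
  care_model("majority-specialist", primary_visits_per_year = 2,
             specialist_visits_per_year = 2,
             initiation_specialist_visits = 1)
}

#' Specify a DMT scenario
#'
#' @param label Scenario name.
#' @param efficacy Proportional slowing of forward progression out of the
#'   treated states (MCI -> mild and mild -> moderate), in \[0, 1).
#' @param uptake An [uptake_schedule()].
#' @param care_model A [care_model()].
#' @param launch_year First year treatment can be given.
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(label, efficacy, uptake, care_model,
                          launch_year = uptake$start_year) {
  stopifnot(efficacy >= 0, efficacy < 1)
  structure(list(label = label, efficacy = efficacy, uptake = uptake,
                 care_model = care_model,
                 launch_year = as.integer(launch_year)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "<scenario_spec> %s: efficacy %.0f%%, uptake -> %.0f%% (%d-%d), %s, launch %d\n",
    x$label, 100 * x$efficacy, 100 * x$uptake$max_uptake,
    x$uptake$start_year, x$uptake$ramp_end_year, x$care_model$label,
    x$launch_year))
  invisible(x)
}

treated_fraction_at <- function(scenario, year) {
  if (year < scenario$launch_year) return(0)
  uptake_at(scenario$uptake, year)
}

#' The four core DMT scenarios
#'
#' High uptake (0% to 58% over 2025-2034) at each efficacy level (30%, 25%,
#' 20%), plus low uptake (0% to 25%) at medium efficacy; all launch in 2025.
#'
#' @param care A [care_model()] attached to every scenario (default
#'   majority-primary).
#' @return Named list of four [scenario_spec()]s.
#' @export
core_scenarios <- function(care = care_model_primary()) {
  high <- uptake_schedule(2025L, 2034L, 0.58)
  low <- uptake_schedule(2025L, 2034L, 0.25)
  list(
    high_uptake_high_efficacy = scenario_spec(
      "high uptake, high efficacy", 0.30, high, care),
    high_uptake_medium_efficacy = scenario_spec(
      "high uptake, medium efficacy", 0.25, high, care),
    high_uptake_low_efficacy = scenario_spec(
      "high uptake, low efficacy", 0.20, high, care),
    low_uptake_medium_efficacy = scenario_spec(
      "low uptake, medium efficacy", 0.25, low, care))
}

#' Treatment-eligible population of a state vector
#'
#' Eligibility covers the MCI-due-to-AD and mild AD dementia states, summed
#' over all age bands and sexes.
#'
#' @param state A [state_vector()].
#' @return Persons eligible for DMT.
#' @export
eligible_count <- function(state) {
  sum(state$counts[c("mci", "mild"), , ])
}

#' Transition rates under partial treatment coverage
#'
#' Treatment slows forward progression out of the treated states: the
#' MCI -> mild and mild -> moderate probabilities are each multiplied by
#' `1 - efficacy * treated_fraction` (the population-weighted mixture of
#' fully-treated and untreated flow). Backward transitions, the
#' moderate -> severe edge (moderate AD is not treatment-eligible), all
#' mortality edges and MCI incidence are unchanged.
#'
#' @param rates A [transition_rates()].
#' @param efficacy Proportional slowing in \[0, 1\].
#' @param treated_fraction Fraction of the eligible states treated, in
#'   \[0, 1\].
#' @return A [transition_rates()] with the two forward edges scaled.
#' @export
effective_rates <- function(rates, efficacy, treated_fraction) {
  stopifnot(efficacy >= 0, efficacy <= 1,
            treated_fraction >= 0, treated_fraction <= 1)
  scale <- 1 - efficacy * treated_fraction
  rates$mci_mild <- rates$mci_mild * scale
  rates$mild_moderate <- rates$mild_moderate * scale
  rates
}

#' Per-year treatment series for a scenario
#'
#' Treatment is memoryless: each year the treated count is the uptake
#' fraction times the eligible population (no individual tracking; people
#' transitioning backward into mild AD remain covered via the same
#' fraction). New starters are the year-on-year increase in the treated
#' count, floored at zero.
#'
#' @param traj A trajectory from [project()].
#' @param scenario A [scenario_spec()].
#' @return A data.frame with columns `year`, `eligible`, `uptake`,
#'   `treated`, `new_starters`.
#' @export
treatment_series <- function(traj, scenario) {
  years <- traj$years
  eligible <- vapply(traj$states, eligible_count, numeric(1))
  uptake <- vapply(years, function(y) treated_fraction_at(scenario, y),
                   numeric(1))
  treated <- uptake * eligible
  new_starters <- pmax(0, diff(c(0, treated)))
  data.frame(year = years, eligible = eligible, uptake = uptake,
             treated = treated, new_starters = new_starters,
             row.names = NULL)
}
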