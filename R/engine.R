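model_states <- function() {
  c("unimpaired", "mci", "mild", "moderate", "severe")
}

dementia_states <- function() c("mild", "moderate", "severe")

#' Construct a state vector (population by state, age band and sex)
#'
#' @param year Calendar year the counts refer to.
#' @param counts Array `[state, band, sex]` (5 x 21 x 2) of persons.
#' @return A `state_vector` object.
#' @export
state_vector <- function(year, counts) {
  stopifnot(all(dim(counts) == c(5L, n_bands(), 2L)))
  dimnames(counts) <- list(state = model_states(), band = band_labels(),
                           sex = model_sexes())
  structure(list(year = as.integer(year), counts = counts),
            class = "state_vector")
}

#' @export
print.state_vector <- function(x, ...) {
  tot <- apply(x$counts, 1, sum)
  cat(sprintf("<state_vector %d>  total %.0f persons\n", x$year, sum(tot)))
  print(round(tot))
  invisible(x)
}

#' Totals by state, and AD dementia totals, for a state vector
#'
#' @param state A [state_vector()].
#' @return `state_totals()`: named numeric of per-state totals.
#'   `dementia_count()`: total persons in mild + moderate + severe AD
#'   dementia.
#' @export
state_totals <- function(state) apply(state$counts, 1, sum)

#' @rdname state_totals
#' @export
dementia_count <- function(state) {
  sum(state$counts[dementia_states(), , ])
}

#' Initialise the baseline state vector from prevalence estimates
#'
#' For each (band, sex) cell: the AD dementia total is prevalence times the
#' national projection, split into mild/moderate/severe by the age-group
#' severity split; the MCI-due-to-AD count is MCI prevalence times the
#' projection (no sex split); the cognitively unimpaired population is the
#' residual against the national projection.
#'
#' @param params A [model_parameters()].
#' @param year Calendar year to initialise at (default the base year).
#' @return A [state_vector()].
#' @export
#' @examples
#' params <- reference_parameters()
#' init <- initialise_states(params)
#' state_totals(init)
initialise_states <- function(params, year = params$base_year) {
  yrs <- population_years(params)
  if (!year %in% yrs)
    stop(sprintf("population projection does not cover year %d", year))
  pop <- params$population[as.character(year), , ]
  split <- expand_severity_split(params$severity)

  ad_total <- params$prev_ad * pop            # [band, sex]
  mci <- params$prev_mci * pop
  counts <- array(0, dim = c(5L, n_bands(), 2L))
  counts[2, , ] <- mci
  for (k in 1:3) counts[k + 2L, , ] <- ad_total * split[, k]
  # residual against the summed states keeps the conservation identity
  # exact even when a published severity row does not sum to exactly 1
  resid <- pop - mci - counts[3, , ] - counts[4, , ] - counts[5, , ]
  if (any(resid < 0)) {
    bad <- which(resid < 0, arr.ind = TRUE)
    stop(sprintf(
      "initialisation error: disease states exceed projection in cell (%s, %s)",
      band_labels()[bad[1, 1]], model_sexes()[bad[1, 2]]))
  }
  counts[1, , ] <- resid
  state_vector(year, counts)
}

# shift 1/5 of each band's occupants up one band; the open top band retains
age_band_shift <- function(x) {
  keep <- x * 4 / 5
  up <- x / 5
  out <- keep
  out[2:n_bands(), ] <- out[2:n_bands(), ] + up[1:(n_bands() - 1L), ]
  out[n_bands(), ] <- out[n_bands(), ] + up[n_bands(), ]
  out
}

#' Advance the cohort one annual cycle
#'
#' Applies, in a fixed documented order: (1) disease-state transitions and
#' disease-state mortality as probability flows; (2) age-specific incidence
#' of MCI due to AD out of the unimpaired population; (3) cohort ageing —
#' each 5-year band passes 1/5 of its survivors to the next band, the open
#' top band retains; (4) recomputation of the unimpaired population as the
#' residual against the next year's national projection (background
#' mortality and migration are therefore implicit in the projection). A
#' negative residual is clamped to zero and reported in the returned
#' object's `warnings` attribute.
#'
#' @param state A [state_vector()].
#' @param rates A [transition_rates()].
#' @param projection_next Matrix `[band, sex]`: national projection for the
#'   next calendar year.
#' @param ageing Logical; disable band ageing (used in equivalence tests).
#' @return A [state_vector()] for `state$year + 1`, with attributes
#'   `incident_mci`, `ad_deaths` and (possibly) `warnings`.
#' @export
step_cycle <- function(state, rates, projection_next, ageing = TRUE) {
  cn <- state$counts
  u <- cn[1, , ]; mci <- cn[2, , ]; mild <- cn[3, , ]
  mod <- cn[4, , ]; sev <- cn[5, , ]

  # (1) disease-state transition flows
  f_mci_mild <- mci * rates$mci_mild
  f_mild_mod <- mild * rates$mild_moderate
  f_mod_sev <- mod * rates$moderate_severe
  f_mod_mild <- mod * rates$moderate_mild
  f_sev_mod <- sev * rates$severe_moderate
  d_mci <- mci * rates$mort_mci
  d_mild <- mild * rates$mort_mild
  d_mod <- mod * rates$mort_moderate
  d_sev <- sev * rates$mort_severe

  mci2 <- mci - f_mci_mild - d_mci
  mild2 <- mild - f_mild_mod - d_mild + f_mci_mild + f_mod_mild
  mod2 <- mod - f_mod_sev - f_mod_mild - d_mod + f_mild_mod + f_sev_mod
  sev2 <- sev - f_sev_mod - d_sev + f_mod_sev

  # (2) incidence of MCI due to AD out of the unimpaired population
  inc <- u * rates$incidence
  mci2 <- mci2 + inc

  # (3) ageing
  if (ageing) {
    mci2 <- age_band_shift(mci2)
    mild2 <- age_band_shift(mild2)
    mod2 <- age_band_shift(mod2)
    sev2 <- age_band_shift(sev2)
  }

  # (4) unimpaired as residual against next year's projection
  resid <- projection_next - mci2 - mild2 - mod2 - sev2
  warnings <- character()
  if (any(resid < 0)) {
    bad <- which(resid < 0, arr.ind = TRUE)
    warnings <- sprintf(
      "residual clamped to 0 in %d cell(s) (first: %s %s, %.3f persons); disease states exceed the national projection — check transition inputs",
      nrow(bad), band_labels()[bad[1, 1]], model_sexes()[bad[1, 2]],
      resid[bad[1, 1], bad[1, 2]])
    resid[resid < 0] <- 0
  }

  counts <- array(0, dim = c(5L, n_bands(), 2L))
  counts[1, , ] <- resid; counts[2, , ] <- mci2; counts[3, , ] <- mild2
  counts[4, , ] <- mod2; counts[5, , ] <- sev2
  out <- state_vector(state$year + 1L, counts)
  attr(out, "incident_mci") <- sum(inc)
  attr(out, "ad_deaths") <- sum(d_mci + d_mild + d_mod + d_sev)
  if (length(warnings)) attr(out, "warnings") <- warnings
  out
}

#' Project the cohort over the model horizon
#'
#' Chains [initialise_states()] and [step_cycle()] across annual cycles.
#' With a [scenario_spec()], each cycle uses [effective_rates()] with the
#' treated fraction given by the scenario's uptake schedule at the cycle's
#' origin year; with `scenario = NULL` the no-treatment baseline is
#' projected. Deterministic given its inputs.
#'
#' @param params A [model_parameters()].
#' @param scenario A [scenario_spec()] or `NULL` for the baseline.
#' @param horizon Final calendar year (default `params$horizon_year`).
#' @return A `trajectory`: list with `years`, `states` (one
#'   [state_vector()] per year), `diagnostics` (per-year incident MCI, AD
#'   deaths), `warnings`, and the `scenario` used (or `NULL`).
#' @export
project <- function(params, scenario = NULL, horizon = params$horizon_year) {
  yrs <- population_years(params)
  if (!all(params$base_year:horizon %in% yrs))
    stop("projection horizon exceeds population projection coverage")

  years <- params$base_year:horizon
  states <- vector("list", length(years))
  names(states) <- years
  states[[1]] <- initialise_states(params, params$base_year)
  diag <- data.frame(year = years, incident_mci = NA_real_,
                     ad_deaths = NA_real_)
  warnings <- character()

  for (i in seq_len(length(years) - 1L)) {
    y <- years[i]
    rates <- params$transitions
    if (!is.null(scenario)) {
      f <- treated_fraction_at(scenario, y)
      if (f > 0)
        rates <- effective_rates(rates, scenario$efficacy, f)
    }
    nxt <- step_cycle(states[[i]], rates,
                      params$population[as.character(y + 1L), , ])
    diag$incident_mci[i + 1L] <- attr(nxt, "incident_mci")
    diag$ad_deaths[i + 1L] <- attr(nxt, "ad_deaths")
    if (!is.null(attr(nxt, "warnings")))
      warnings <- c(warnings, sprintf("%d: %s", y + 1L,
                                      attr(nxt, "warnings")))
    states[[i + 1L]] <- nxt
  }
  structure(list(years = years, states = states, diagnostics = diag,
                 warnings = warnings, scenario = scenario),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  lab <- if (is.null(x$scenario)) "baseline (no DMT)" else x$scenario$label
  n <- length(x$years)
  cat(sprintf("<trajectory> %s, %d-%d\n", lab, x$years[1], x$years[n]))
  cat(sprintf("  AD dementia: %.0f (%d) -> %.0f (%d)\n",
              dementia_count(x$states[[1]]), x$years[1],
              dementia_count(x$states[[n]]), x$years[n]))
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Per-year AD dementia totals of a trajectory
#'
#' @param traj A trajectory from [project()].
#' @return Named numeric vector: total mild + moderate + severe AD dementia
#'   persons per calendar year.
#' @export
dementia_series <- function(traj) {
  vapply(traj$states, dementia_count, numeric(1))
}

#' Export a trajectory as a long-format data.frame / CSV
#'
#' Columns `year, state, age_band, sex, persons`.
#'
#' @param traj A trajectory from [project()].
#' @param path Optional CSV path; when given the table is also written.
#' @return The long-format data.frame, invisibly when `path` is given.
#' @export
trajectory_long <- function(traj, path = NULL) {
  rows <- lapply(traj$states, function(st) {
    g <- expand.grid(state = model_states(), age_band = band_labels(),
                     sex = model_sexes(), stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
    g$year <- st$year
    g$persons <- as.vector(st$counts)
    g[, c("year", "state", "age_band", "sex", "persons")]
  })
  long <- do.call(rbind, rows)
  rownames(long) <- NULL
  if (!is.null(path)) {
    utils::write.csv(long, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    return(invisible(long))
  }
  long
}
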