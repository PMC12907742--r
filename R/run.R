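#' Run the baseline and a scenario grid, writing all outputs
#'
#' Validates the parameter bundle, projects the no-treatment baseline once
#' and each scenario once, and writes per-scenario trajectory CSVs
#' (`year, state, age_band, sex, persons`), cost CSVs (`year, scenario,
#' health_gbp, social_gbp, followup_gbp, drug_gbp, total_gbp,
#' cumulative_gbp, offset_vs_baseline_gbp`), offset CSVs, a summary grid in
#' CSV and JSON, a manifest JSON and a plain-text log. Outputs are
#' deterministic given the config (CSV outputs are byte-identical across
#' reruns).
#'
#' @param config A [model_parameters()] object or a path to a config file
#'   for [load_parameters()].
#' @param out_dir Output directory (created if missing).
#' @param scenarios Named list of [scenario_spec()]s; default the four core
#'   scenarios. An empty list runs the baseline only.
#' @param drug_price Optional annual DMT price (GBP); populates the drug
#'   cost column. Omitted, drug costs are zero.
#' @param horizon Final calendar year; default the bundle's horizon year.
#' @param seed Seed recorded in the manifest (used by callers generating
#'   synthetic inputs).
#' @param quiet Suppress the printed summary.
#' @return The run manifest (list), invisibly. Every file listed in
#'   `manifest$files` exists after a successful run.
#' @export
run_model <- function(config, out_dir, scenarios = core_scenarios(),
                      drug_price = NULL, horizon = NULL, seed = NULL,
                      quiet = FALSE) {
  params <- if (inherits(config, "model_parameters")) config
            else load_parameters(config)
  if (!is.null(drug_price)) params$costs$drug_price_annual <- drug_price
  if (is.null(horizon)) horizon <- params$horizon_year

  viol <- validate_parameters(params)
  if (nrow(viol) > 0)
    stop(paste0("parameter validation failed:\n",
                paste(sprintf("  %s [%s]: %s", viol$field, viol$rule,
                              viol$message), collapse = "\n")),
         call. = FALSE)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  warnings <- character()
  add_file <- function(path) files <<- c(files, path)

  baseline <- project(params, scenario = NULL, horizon = horizon)
  baseline_cs <- cost_series(baseline, params)
  warnings <- c(warnings, baseline$warnings)

  tpath <- file.path(out_dir, "trajectory_baseline.csv")
  trajectory_long(baseline, tpath); add_file(tpath)
  write_cost_csv(baseline_cs, "baseline", NULL,
                 file.path(out_dir, "costs_baseline.csv"))
  add_file(file.path(out_dir, "costs_baseline.csv"))

  summary_rows <- list(summary_row("baseline", baseline, baseline_cs, NULL))
  for (nm in names(scenarios)) {
    sc <- scenarios[[nm]]
    traj <- project(params, scenario = sc, horizon = horizon)
    warnings <- c(warnings, traj$warnings)
    ts <- treatment_series(traj, sc)
    cs <- cost_series(traj, params, treatment = ts)
    off <- offsets(baseline_cs, cs, ts)

    tp <- file.path(out_dir, sprintf("trajectory_%s.csv", nm))
    trajectory_long(traj, tp); add_file(tp)
    cp <- file.path(out_dir, sprintf("costs_%s.csv", nm))
    write_cost_csv(cs, nm, off, cp); add_file(cp)
    op <- file.path(out_dir, sprintf("offsets_%s.csv", nm))
    utils::write.csv(cbind(off, treated = ts$treated), op,
                     row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    add_file(op)
    summary_rows <- c(summary_rows, list(summary_row(nm, traj, cs, off)))
  }

  summary <- do.call(rbind, summary_rows)
  spath_csv <- file.path(out_dir, "summary.csv")
  utils::write.csv(summary, spath_csv, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  add_file(spath_csv)
  spath_json <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, spath_json, digits = NA, pretty = TRUE)
  add_file(spath_json)

  manifest <- list(
    config = if (is.character(config)) config else "<in-memory parameters>",
    scenarios = names(scenarios),
    seed = seed,
    version = as.character(utils::packageVersion("adcohort")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    horizon = horizon,
    drug_price = params$costs$drug_price_annual,
    out_dir = out_dir,
    files = files,
    warnings = warnings)
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  manifest$files <- c(manifest$files, mpath)

  log_lines <- c(sprintf("adcohort run %s", manifest$timestamp),
                 sprintf("scenarios: %s",
                         paste(c("baseline", names(scenarios)),
                               collapse = ", ")),
                 sprintf("horizon: %d", horizon),
                 if (length(warnings)) c("warnings:", paste(" ", warnings))
                 else "warnings: none")
  writeLines(log_lines, file.path(out_dir, "run.log"))
  manifest$files <- c(manifest$files, file.path(out_dir, "run.log"))

  if (!quiet) {
    cat(sprintf("Projection %d-%d, %d scenario(s) + baseline\n",
                params$base_year, horizon, length(scenarios)))
    print(summary, digits = 10)
  }
  invisible(manifest)
}

summary_row <- function(label, traj, cs, off) {
  n <- length(traj$years)
  data.frame(
    scenario = label,
    ad_dementia_horizon = dementia_count(traj$states[[n]]),
    total_cost_horizon_gbp = cs$total[n],
    cumulative_cost_gbp = cs$cumulative[n],
    cumulative_offset_gbp = if (is.null(off)) 0 else off$cumulative_offset[n],
    stringsAsFactors = FALSE)
}

write_cost_csv <- function(cs, label, off, path) {
  out <- data.frame(year = cs$year, scenario = label,
                    health_gbp = cs$health, social_gbp = cs$social,
                    followup_gbp = cs$followup, drug_gbp = cs$drug,
                    total_gbp = cs$total, cumulative_gbp = cs$cumulative,
                    offset_vs_baseline_gbp = if (is.null(off)) 0
                                             else off$offset)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Summary grid of a finished run
#'
#' Rebuilds, from the files a [run_model()] manifest points at, a
#' three-panel grid with years as columns (base, +5, +10, +15, +20) and
#' scenarios as rows: estimated AD dementia counts, count changes versus
#' baseline, and annual total-cost changes versus baseline. Count panels
#' are persons; the cost-change panel is reported in billions of GBP
#' rounded to 0.1.
#'
#' @param manifest A manifest from [run_model()], or a path to a
#'   `manifest.json`.
#' @return A data.frame with columns `panel`, `scenario` and one column per
#'   reporting year. The change panels are, by construction, the
#'   elementwise difference of the count/cost panels against the baseline
#'   row.
#' @export
summarise_run <- function(manifest) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  out_dir <- manifest$out_dir
  years_of <- function(df) sort(unique(df$year))

  read_traj_counts <- function(label) {
    path <- file.path(out_dir, sprintf("trajectory_%s.csv", label))
    if (!file.exists(path))
      stop(sprintf("summary error: missing output file %s", path))
    long <- utils::read.csv(path, stringsAsFactors = FALSE)
    dem <- long[long$state %in% dementia_states(), ]
    stats::aggregate(persons ~ year, dem, sum)
  }
  read_costs <- function(label) {
    path <- file.path(out_dir, sprintf("costs_%s.csv", label))
    if (!file.exists(path))
      stop(sprintf("summary error: missing output file %s", path))
    utils::read.csv(path, stringsAsFactors = FALSE)
  }

  base_counts <- read_traj_counts("baseline")
  yrs <- years_of(base_counts)
  report_years <- yrs[yrs %in% seq(min(yrs), max(yrs), by = 5L)]
  labels <- c("baseline", manifest$scenarios)
  names(labels) <- labels

  pick <- function(df, col) df[[col]][match(report_years, df$year)]
  counts <- lapply(labels, function(l) pick(read_traj_counts(l), "persons"))
  costs <- lapply(labels, function(l) pick(read_costs(l), "total_gbp"))

  grid_panel <- function(panel, values) {
    df <- data.frame(panel = panel, scenario = names(values),
                     stringsAsFactors = FALSE)
    m <- do.call(rbind, values)
    colnames(m) <- paste0("y", report_years)
    cbind(df, as.data.frame(m))
  }
  out <- grid_panel("ad_dementia_count", counts)
  if (length(counts) > 1L) {
    p2_vals <- lapply(counts[-1], function(v) v - counts[[1]])
    p3_vals <- lapply(costs[-1],
                      function(v) round((v - costs[[1]]) / 1e9, 1))
    out <- rbind(out,
                 grid_panel("count_change_vs_baseline", p2_vals),
                 grid_panel("annual_cost_change_bn", p3_vals))
  }
  rownames(out) <- NULL
  out
}
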