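# Published UK baseline estimates: AD dementia prevalence, MCI-due-to-AD
# prevalence and incidence, per-person-per-year HCRU costs (all-England and
# all-severity AD), severity splits and severity cost ratios, social-care
# unit costs and follow-up visit costs. Age rows run 30-34 .. 100+; bands
# below 30 carry zero prevalence and incidence (no published data below 30).

ref_band_values <- function(x) {
  stopifnot(length(x) == 15L)
  c(rep(0, 6L), x)  # 0-4 .. 25-29 zeroed, then 30-34 .. 100+
}

ref_band_costs <- function(x) {
  # costs have no published rows below 30; extend the 30-34 value downward
  # (these cells never touch disease states, which are empty below 30)
  stopifnot(length(x) == 15L)
  c(rep(x[1], 6L), x)
}

reference_prev_ad <- function() {
  stratified_table(cbind(
    male = ref_band_values(c(0.0001, 0.0003, 0.0005, 0.0009, 0.0016, 0.0028,
                             0.0052, 0.0078, 0.0195, 0.0338, 0.0689, 0.0832,
                             0.1112, 0.1112, 0.1112)),
    female = ref_band_values(c(0.0002, 0.0003, 0.0005, 0.0010, 0.0018,
                               0.0033, 0.0059, 0.0117, 0.0163, 0.0403,
                               0.0618, 0.1177, 0.2275, 0.2275, 0.2275))),
    "probability")
}

reference_prev_mci <- function() {
  ref_band_values(c(0.0039, 0.0054, 0.0075, 0.0103, 0.0143, 0.0197, 0.0297,
                    0.0416, 0.0553, 0.0886, 0.1630, 0.2612, 0.2757, 0.2757,
                    0.2757))
}

reference_incidence <- function() {
  ref_band_values(c(0.0001, 0.0002, 0.0003, 0.0005, 0.0009, 0.0015, 0.0024,
                    0.0043, 0.0078, 0.0135, 0.0265, 0.0417, 0.0745, 0.1218,
                    0.1990))
}

reference_costs <- function(drug_price_annual = NULL) {
  cost_parameters(
    england_hcru = stratified_table(cbind(
      male = ref_band_costs(c(693.86, 734.49, 821.90, 1045.25, 1222.83,
                              1448.22, 1663.87, 2412.88, 2795.88, 3621.93,
                              4181.89, 4781.36, 4797.56, 4548.80, 3218.98)),
      female = ref_band_costs(c(1789.63, 1515.61, 1268.05, 1364.51, 1502.76,
                                1615.18, 1698.39, 2221.96, 2479.90, 3027.38,
                                3505.93, 3891.96, 3461.62, 3219.13,
                                2088.91))),
      "gbp_per_person_year"),
    ad_hcru = ref_band_costs(c(2626.96, 2626.96, 2626.96, 2626.96, 2740.08,
                               2996.39, 3327.09, 3740.76, 4019.29, 4130.35,
                               4643.33, 5001.80, 5547.85, 5460.43, 4465.27)),
    social_general = c(under18 = 0, adult = 200.26, senior = 499.89),
    social_ad = c(male = 12526, female = 12480),
    social_utilisation = 0.48,
    health_ratios = c(mild = 0.5548, moderate = 1.4829, severe = 1.7597),
    social_ratios = c(mild = 0.4261, moderate = 1.7049, severe = 1.7622),
    primary_visit_cost = 33,
    specialist_visit_cost = 465,
    drug_price_annual = drug_price_annual)
}

reference_severity <- function() {
  severity_split(groups_lower = c(35L, 65L, 75L, 85L),
                 mild = c(0.5882, 0.1792, 0.1897, 0.1470),
                 moderate = c(0.3529, 0.4083, 0.4018, 0.3153),
                 severe = c(0.0588, 0.4125, 0.4084, 0.5378))
}

#' Illustrative placeholder transition probabilities
#'
#' Annual transition probabilities between disease states are not part of the
#' published parameter tables this package packages; they must be supplied by
#' the user. These defaults are illustrative placeholders in a clinically
#' plausible range — NOT published values — chosen so that disease-state
#' totals stay well below national population totals (no residual clamping
#' in reference runs). The age-specific MCI incidence column IS a published
#' table and is attached here.
#'
#' @return A [transition_rates()] object, provenance-tagged `"placeholder"`
#'   everywhere except the published incidence column.
#' @export
placeholder_transitions <- function() {
  transition_rates(
    mci_mild = 0.35, mild_moderate = 0.45, moderate_severe = 0.35,
    moderate_mild = 0.05, severe_moderate = 0.05,
    mort_mci = 0.10, mort_mild = 0.12, mort_moderate = 0.20,
    mort_severe = 0.30,
    incidence = reference_incidence())
}

#' Packaged reference parameter bundle
#'
#' Bundles the published UK baseline estimates (prevalences, MCI incidence,
#' HCRU and social-care costs, severity splits and cost ratios, follow-up
#' visit costs) with placeholder transition probabilities (see
#' [placeholder_transitions()]) and a population projection. The default
#' population is generated by [synthetic_population_projection()] — a
#' synthetic stand-in for national projections, tagged `"synthetic"` in the
#' provenance log — so the bundle is runnable with no external data; pass a
#' real projection array to use official figures.
#'
#' @param population Optional population array `[year, band, sex]` covering
#'   `base_year:horizon_year`; defaults to a synthetic projection.
#' @param drug_price_annual Optional annual DMT price (GBP per treated
#'   person-year); absent by default, which disables drug-cost outputs.
#' @param base_year,horizon_year Projection window (annual cycles).
#' @return A [model_parameters()] object whose `provenance` field tags each
#'   parameter group as `"published"`, `"placeholder"` or `"synthetic"`.
#' @export
#' @examples
#' params <- reference_parameters()
#' params$prev_ad["80-84", "male"]   # 0.0689
#' validate_parameters(params)      # zero rows
reference_parameters <- function(population = NULL,
                                 drug_price_annual = NULL,
                                 base_year = 2020L, horizon_year = 2040L) {
  pop_prov <- if (is.null(population)) "synthetic" else "user-supplied"
  if (is.null(population)) {
    population <- synthetic_population_projection(
      synthetic_population_config(base_year = base_year,
                                  horizon_year = horizon_year))
  }
  model_parameters(
    population = population,
    prev_ad = reference_prev_ad(),
    prev_mci = reference_prev_mci(),
    severity = reference_severity(),
    transitions = placeholder_transitions(),
    costs = reference_costs(drug_price_annual),
    base_year = base_year, horizon_year = horizon_year,
    currency = "GBP 2019",
    provenance = c(population = pop_prov,
                   prevalence = "published",
                   incidence = "published",
                   severity = "published",
                   costs = "published",
                   transitions = "placeholder"))
}
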