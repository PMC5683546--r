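# The treatment cascade walked by both the deterministic cohort arithmetic and
# the microsimulation oracle. A single walker encodes the event tree; the two
# uses differ only in the `split` operator (expectation vs binomial draws), so
# structural drift between model and oracle is impossible by construction.

#' Allocate the birth cohort over settings, PPH and cause
#'
#' Splits annual live births into home/clinic/hospital deliveries, applies the
#' per-setting PPH incidence, and attributes the atonic fraction.
#'
#' @param region A [region_inputs()] object.
#' @return A data frame with one row per setting and columns `setting`,
#'   `births`, `pph_cases`, `atonic_cases`. Counts are real-valued; rounding is
#'   a reporting concern.
#' @examples
#' allocate_cohort(region_inputs())
#' @export
allocate_cohort <- function(region) {
  stopifnot(inherits(region, "region_inputs"))
  births <- region$live_births * region$setting_shares
  pph <- births * region$pph_rate
  atonic <- pph * region$atonic_fraction
  data.frame(setting = SETTINGS, births = unname(births),
             pph_cases = unname(pph), atonic_cases = unname(atonic),
             stringsAsFactors = FALSE)
}

# Expectation split: deterministic cohort arithmetic over length-3 vectors.
split_expectation <- function(n, p) n * p

# Sampling split: one binomial draw per setting; n must be integer counts.
split_binomial <- function(n, p) stats::rbinom(length(n), size = n, prob = p)

# Walk the full event tree for per-setting entering-birth counts.
# `births` is a length-3 named vector (home, clinic, hospital); `split(n, p)`
# returns the "yes" branch count, vectorised over settings.
walk_cascade <- function(births, region, ubt, hidden, constants,
                         population_filter, ut_coverage, split) {
  pph <- split(births, region$pph_rate)
  atonic <- split(pph, rep(region$atonic_fraction, 3L))

  # First line: uterotonic drugs (coverage x efficacy), resolved cases stay
  # below the severity threshold.
  resolved_ut <- split(atonic, ut_coverage * hidden$uterotonic_efficacy)
  failed <- atonic - resolved_ut

  # Severity at second line: a fixed fraction is already past 1000 mL.
  presevere <- split(failed, rep(hidden$presevere_fraction, 3L))
  nonsevere <- failed - presevere

  # Second line: UBT, gated by penetration x utilization; the nonsevere-only
  # scenario withholds the device from the already-severe stratum.
  if (is.null(ubt)) {
    coverage <- c(home = 0, clinic = 0, hospital = 0)
    eff_ns <- 0
    eff_sev <- 0
  } else {
    coverage <- ubt$penetration * ubt$utilization
    eff_ns <- ubt$efficacy_nonsevere
    eff_sev <- if (population_filter == "nonsevere_only") 0 else ubt$efficacy_severe
  }
  resolved_ubt_severe <- split(presevere, coverage * eff_sev)
  severe_unresolved0 <- presevere - resolved_ubt_severe
  resolved_ubt_nonsevere <- split(nonsevere, coverage * eff_ns)
  nonsevere_unresolved <- nonsevere - resolved_ubt_nonsevere

  # Unresolved nonsevere cases may cross the severity threshold.
  progressed <- split(nonsevere_unresolved, rep(hidden$progression_prob, 3L))
  nonsevere_refractory <- nonsevere_unresolved - progressed
  severe_unresolved <- severe_unresolved0 + progressed

  # Last resort: surgery for refractory cases (severe or not) with per-setting
  # access; fatality by terminal state.
  surgeries_severe <- split(severe_unresolved, hidden$surgery_access)
  severe_no_surgery <- severe_unresolved - surgeries_severe
  surgeries_nonsevere <- split(nonsevere_refractory, hidden$surgery_access)
  nonsevere_no_surgery <- nonsevere_refractory - surgeries_nonsevere

  d1 <- rep(hidden$cfr_severe_surgery, 3L)
  d0 <- rep(hidden$cfr_severe_no_surgery, 3L)
  d2 <- rep(hidden$cfr_nonsevere_resolved, 3L)
  deaths_surg_severe <- split(surgeries_severe, d1)
  deaths_no_surg_severe <- split(severe_no_surgery, d0)
  deaths_surg_nonsevere <- split(surgeries_nonsevere, d1)
  nonsevere_enders <- resolved_ut + resolved_ubt_nonsevere + nonsevere_no_surgery
  deaths_nonsevere_mild <- split(nonsevere_enders, d2)
  deaths_resolved_severe <- split(resolved_ubt_severe, d2)

  severe_cases_total <- presevere + progressed
  deaths_severe <- deaths_surg_severe + deaths_no_surg_severe + deaths_resolved_severe
  deaths_nonsevere <- deaths_surg_nonsevere + deaths_nonsevere_mild
  deaths <- deaths_severe + deaths_nonsevere
  severe_survivors <- severe_cases_total - deaths_severe

  data.frame(
    setting = SETTINGS,
    births = unname(births),
    pph_cases = unname(pph),
    atonic_cases = unname(atonic),
    cases_entering = unname(atonic),
    resolved_by_uterotonic = unname(resolved_ut),
    resolved_by_ubt_nonsevere = unname(resolved_ubt_nonsevere),
    resolved_by_ubt_severe = unname(resolved_ubt_severe),
    resolved_by_ubt = unname(resolved_ubt_nonsevere + resolved_ubt_severe),
    progressed_to_severe = unname(progressed),
    nonsevere_refractory = unname(nonsevere_refractory),
    severe_unresolved = unname(severe_unresolved),
    surgeries_severe = unname(surgeries_severe),
    surgeries_nonsevere = unname(surgeries_nonsevere),
    surgeries = unname(surgeries_severe + surgeries_nonsevere),
    deaths_severe = unname(deaths_severe),
    deaths_nonsevere = unname(deaths_nonsevere),
    deaths = unname(deaths),
    severe_cases_total = unname(severe_cases_total),
    severe_survivors = unname(severe_survivors),
    anemia_cases = unname(severe_survivors * constants$anemia_fraction),
    stringsAsFactors = FALSE
  )
}

# Fields summed into the totals block (anemia handled from severe_survivors).
TOTAL_FIELDS <- c("births", "pph_cases", "atonic_cases", "cases_entering",
                  "resolved_by_uterotonic", "resolved_by_ubt_nonsevere",
                  "resolved_by_ubt_severe", "resolved_by_ubt",
                  "progressed_to_severe", "nonsevere_refractory",
                  "severe_unresolved", "surgeries_severe",
                  "surgeries_nonsevere", "surgeries", "deaths_severe",
                  "deaths_nonsevere", "deaths", "severe_cases_total",
                  "severe_survivors", "anemia_cases")

build_cascade_result <- function(settings_df, hidden, constants, scenario_name,
                                 population_filter, region) {
  totals <- as.list(colSums(settings_df[TOTAL_FIELDS]))
  totals$nonatonic_deaths <- hidden$nonatonic_death_load
  totals$total_pph_deaths <- totals$deaths + hidden$nonatonic_death_load
  structure(
    list(settings = settings_df, totals = totals, scenario = scenario_name,
         population_filter = population_filter, constants = constants,
         live_births = region$live_births),
    class = "cascade_result"
  )
}

#' Run the PPH treatment cascade for a birth cohort
#'
#' Propagates the annual cohort through delivery settings, PPH onset, cause
#' attribution, first-line uterotonic treatment, severity dynamics, an
#' optional UBT step, and last-resort surgery, down to deaths, surgeries,
#' severe hemorrhage cases and severe anemia. All flows are expectations
#' (real-valued counts); see [microsim_oracle()] for the stochastic
#' individual-level counterpart built on the same event tree.
#'
#' @param region A [region_inputs()] object.
#' @param ubt A [ubt_spec()] object, or `NULL` for the no-UBT baseline.
#' @param hidden A [hidden_params()] object.
#' @param constants A [model_constants()] object.
#' @param population_filter `"all"` applies the UBT to both severity strata;
#'   `"nonsevere_only"` withholds it from cases already above 1000 mL (severe
#'   efficacy set to zero, nonsevere pathway unchanged).
#' @param ut_coverage Per-setting combined uterotonic coverage; defaults to
#'   [uterotonic_coverage()].
#' @param scenario_name Label carried into reports.
#' @return An object of class `cascade_result`: `$settings`, a data frame of
#'   per-setting flow counts; `$totals`, the aggregate including the additive
#'   non-atonic death load.
#' @examples
#' base <- run_cascade(region_inputs(), ubt_spec(), hidden_params())
#' noubt <- run_cascade(region_inputs(), NULL, hidden_params())
#' compare_scenarios(noubt, base)
#' @export
run_cascade <- function(region, ubt = NULL, hidden = hidden_params(),
                        constants = model_constants(),
                        population_filter = c("all", "nonsevere_only"),
                        ut_coverage = uterotonic_coverage(),
                        scenario_name = if (is.null(ubt)) "baseline" else ubt$name) {
  stopifnot(inherits(region, "region_inputs"), inherits(hidden, "hidden_params"),
            inherits(constants, "model_constants"))
  if (!is.null(ubt)) stopifnot(inherits(ubt, "ubt_spec"))
  population_filter <- match.arg(population_filter)
  ut_coverage <- assert_setting_map(ut_coverage, "ut_coverage")

  births <- region$live_births * region$setting_shares
  settings_df <- walk_cascade(births, region, ubt, hidden, constants,
                              population_filter, ut_coverage, split_expectation)
  build_cascade_result(settings_df, hidden, constants, scenario_name,
                       population_filter, region)
}

#' Severe anemia cases implied by a severe hemorrhage count
#'
#' Applies the fixed anemia fraction (12% of severe-hemorrhage sufferers) to a
#' count of severe cases. Returns the unrounded product; rounding is left to
#' report formatting.
#'
#' @param severe_count Non-negative count of severe hemorrhage cases.
#' @param constants A [model_constants()] object.
#' @return `severe_count * anemia_fraction`.
#' @examples
#' anemia_from_severe(5287) # 634.44, reported rounded as 634
#' @export
anemia_from_severe <- function(severe_count, constants = model_constants()) {
  assert_nonneg(severe_count, "severe_count")
  stopifnot(inherits(constants, "model_constants"))
  severe_count * constants$anemia_fraction
}

#' @export
print.cascade_result <- function(x, digits = 0, ...) {
  cat("PPH treatment-cascade result: ", x$scenario,
      " (filter: ", x$population_filter, ")\n", sep = "")
  t <- x$totals
  fmt <- function(v) formatC(round(v, digits), format = "f", digits = digits,
                             big.mark = ",")
  cat("  live births:        ", fmt(t$births), "\n", sep = "")
  cat("  PPH cases:          ", fmt(t$pph_cases), "\n", sep = "")
  cat("  atonic PPH cases:   ", fmt(t$atonic_cases), "\n", sep = "")
  cat("  severe cases:       ", fmt(t$severe_cases_total), "\n", sep = "")
  cat("  surgeries:          ", fmt(t$surgeries), "\n", sep = "")
  cat("  atonic PPH deaths:  ", fmt(t$deaths), "\n", sep = "")
  cat("  total PPH deaths:   ", fmt(t$total_pph_deaths),
      "  (incl. ", fmt(t$nonatonic_deaths), " non-atonic)\n", sep = "")
  cat("  severe anemia:      ", fmt(t$anemia_cases), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.cascade_result <- function(x, ...) {
  x$settings
}
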