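#' Regional demographic and epidemiologic inputs
#'
#' Bundles the printed model inputs that drive the cohort: annual live births,
#' the share of deliveries by care setting, per-setting PPH incidence among
#' deliveries, and the fraction of PPH attributable to uterine atony. Defaults
#' are the sub-Saharan Africa values for 2018 used throughout the package.
#'
#' @param live_births Annual live births (count).
#' @param setting_shares Named proportions over `home`, `clinic`, `hospital`;
#'   must sum to 1 (tolerance 1e-9).
#' @param pph_rate Named per-setting proportion of deliveries resulting in PPH.
#' @param atonic_fraction Proportion of PPH due to atonic uterus.
#' @param year_label Free-text label for the reference year.
#' @return An object of class `region_inputs`.
#' @examples
#' region_inputs()
#' allocate_cohort(region_inputs())
#' @export
region_inputs <- function(live_births = 34806654,
                          setting_shares = c(home = 0.50, clinic = 0.35, hospital = 0.15),
                          pph_rate = c(home = 0.12, clinic = 0.10, hospital = 0.08),
                          atonic_fraction = 0.90,
                          year_label = "2018") {
  assert_nonneg(live_births, "live_births")
  setting_shares <- assert_setting_map(setting_shares, "setting_shares")
  if (abs(sum(setting_shares) - 1) > 1e-9) {
    stop_val("setting_shares must sum to 1 (got ", format(sum(setting_shares)), ")")
  }
  pph_rate <- assert_setting_map(pph_rate, "pph_rate")
  assert_proportion(atonic_fraction, "atonic_fraction")
  structure(
    list(live_births = live_births, setting_shares = setting_shares,
         pph_rate = pph_rate, atonic_fraction = atonic_fraction,
         year_label = as.character(year_label)),
    class = "region_inputs"
  )
}

#' Intervention coverage-and-efficacy specification
#'
#' Describes one treatment step by the standard coverage cascade: penetration
#' (availability in a setting), utilization (appropriate use given
#' availability) and efficacy (probability of arresting the hemorrhage given
#' use), the latter stratified by severity at application (blood loss below or
#' above the 1000 mL threshold). Defaults are the base-case UBT assumptions:
#' no availability at home births, 60%/80% penetration and 85% utilization in
#' clinics/hospitals, 85% nonsevere efficacy and 70% severe efficacy.
#'
#' @param penetration,utilization Named per-setting proportions.
#' @param efficacy_nonsevere,efficacy_severe Proportions in \[0, 1\].
#' @param name Label used in reports.
#' @return An object of class `ubt_spec`.
#' @export
ubt_spec <- function(penetration = c(home = 0, clinic = 0.60, hospital = 0.80),
                     utilization = c(home = 0, clinic = 0.85, hospital = 0.85),
                     efficacy_nonsevere = 0.85,
                     efficacy_severe = 0.70,
                     name = "UBT") {
  penetration <- assert_setting_map(penetration, "penetration")
  utilization <- assert_setting_map(utilization, "utilization")
  assert_proportion(efficacy_nonsevere, "efficacy_nonsevere")
  assert_proportion(efficacy_severe, "efficacy_severe")
  structure(
    list(name = as.character(name), penetration = penetration,
         utilization = utilization, efficacy_nonsevere = efficacy_nonsevere,
         efficacy_severe = efficacy_severe),
    class = "ubt_spec"
  )
}

#' Unpublished cascade parameters subject to calibration
#'
#' The cohort framework this package re-implements publishes its demographic
#' inputs and the UBT coverage assumptions, but not its internal treatment
#' parameters. Those are collected here: first-line uterotonic efficacy, when
#' severity is realized (the fraction of atonic PPH already past 1000 mL at
#' second line, and the probability an untreated nonsevere case progresses
#' across the threshold), per-setting access to surgical care for refractory
#' cases, case fatality rates, and an additive load of baseline PPH deaths
#' from non-atonic causes (retained placenta, lacerations) that the UBT does
#' not touch but that enters the mortality-reduction denominator.
#'
#' Defaults are order-of-magnitude placeholders inside plausible clinical
#' ranges; analyses intended to reproduce published aggregates should use
#' parameters fitted with [ubt_calibrate()].
#'
#' @param uterotonic_efficacy Probability a uterotonic drug, when received,
#'   resolves the hemorrhage.
#' @param presevere_fraction Fraction of atonic PPH already severe (>1000 mL)
#'   when second-line treatment begins.
#' @param progression_prob Probability an unresolved nonsevere case crosses
#'   the 1000 mL threshold.
#' @param surgery_access Named per-setting proportion of refractory cases
#'   reaching surgical care (the clinic value folds in transfer success).
#' @param cfr_severe_no_surgery,cfr_severe_surgery Case fatality of unresolved
#'   severe hemorrhage without / with surgical care; the surgical rate may not
#'   exceed the non-surgical rate.
#' @param cfr_nonsevere_resolved Residual case fatality among cases ending
#'   below the severity threshold.
#' @param nonatonic_death_load Baseline PPH deaths per year from non-atonic
#'   causes (count, unaffected by the UBT).
#' @return An object of class `hidden_params`.
#' @export
hidden_params <- function(uterotonic_efficacy = 0.85,
                          presevere_fraction = 0.15,
                          progression_prob = 0.30,
                          surgery_access = c(home = 0.05, clinic = 0.30, hospital = 0.80),
                          cfr_severe_no_surgery = 0.20,
                          cfr_severe_surgery = 0.05,
                          cfr_nonsevere_resolved = 0.001,
                          nonatonic_death_load = 6000) {
  assert_proportion(uterotonic_efficacy, "uterotonic_efficacy")
  assert_proportion(presevere_fraction, "presevere_fraction")
  assert_proportion(progression_prob, "progression_prob")
  surgery_access <- assert_setting_map(surgery_access, "surgery_access")
  assert_proportion(cfr_severe_no_surgery, "cfr_severe_no_surgery")
  assert_proportion(cfr_severe_surgery, "cfr_severe_surgery")
  assert_proportion(cfr_nonsevere_resolved, "cfr_nonsevere_resolved")
  assert_nonneg(nonatonic_death_load, "nonatonic_death_load")
  if (cfr_severe_surgery > cfr_severe_no_surgery + 1e-12) {
    stop_val("cfr_severe_surgery must not exceed cfr_severe_no_surgery")
  }
  structure(
    list(uterotonic_efficacy = uterotonic_efficacy,
         presevere_fraction = presevere_fraction,
         progression_prob = progression_prob,
         surgery_access = surgery_access,
         cfr_severe_no_surgery = cfr_severe_no_surgery,
         cfr_severe_surgery = cfr_severe_surgery,
         cfr_nonsevere_resolved = cfr_nonsevere_resolved,
         nonatonic_death_load = nonatonic_death_load),
    class = "hidden_params"
  )
}

#' Fixed model constants
#'
#' The severity threshold defining severe PPH (blood loss above 1000 mL) and
#' the fraction of severe-hemorrhage sufferers who develop severe anemia.
#'
#' @param severe_threshold_ml Severity threshold in mL; fixed at 1000.
#' @param anemia_fraction Proportion developing severe anemia after severe
#'   hemorrhage; fixed at 0.12.
#' @return An object of class `model_constants`.
#' @export
model_constants <- function(severe_threshold_ml = 1000, anemia_fraction = 0.12) {
  assert_nonneg(severe_threshold_ml, "severe_threshold_ml")
  assert_proportion(anemia_fraction, "anemia_fraction")
  structure(list(severe_threshold_ml = severe_threshold_ml,
                 anemia_fraction = anemia_fraction),
            class = "model_constants")
}

#' Default first-line uterotonic coverage
#'
#' Combined penetration-times-utilization of uterotonic drugs per setting.
#' The package matches uterotonic coverage to the UBT penetration assumptions
#' (none at home, 60% in clinics, 80% in hospitals), modelling a device made
#' available wherever uterotonics are already in use; uterotonic *efficacy*
#' remains a hidden, calibrated parameter.
#'
#' @return Named numeric vector over `home`, `clinic`, `hospital`.
#' @export
uterotonic_coverage <- function() {
  c(home = 0, clinic = 0.60, hospital = 0.80)
}
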