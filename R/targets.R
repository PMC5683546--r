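# Published aggregate outputs used as calibration targets, and their
# evaluation from the scenario engine.

#' The published aggregate outputs as a calibration target table
#'
#' Eight aggregates are printed for the 2018 sub-Saharan Africa cohort:
#' base-scenario lives saved (6547), the percent reduction in PPH mortality
#' (11), surgeries averted (10,823), severe anemia cases averted (634),
#' nonsevere-only lives saved (1148) and severe cases averted (5287), the
#' increase in lives saved from base to optimistic severe efficacy (~800),
#' and the percent increase in lives saved at 95% nonsevere efficacy (10).
#'
#' Tolerances encode the published precision: 0.5 on counts and percents
#' (final-integer rounding), 50 on the "approximately 800" delta. Weights are
#' `(observed / tolerance)^2`, so the weighted squared relative-error
#' objective of [calibrate_hidden()] reduces to the usual chi-square
#' `sum(((model - observed) / tolerance)^2)`.
#'
#' The `fit` flag marks targets carrying independent information for the fit.
#' `pct_gain_eff95` is excluded (flag `FALSE`, residual still reported): in a
#' one-pass cascade the lives-saved response is affine in the nonsevere
#' efficacy, so this percentage is an algebraic function of `lives_saved` and
#' `lives_saved_nonsevere` — roughly `100 * (1148 / 0.85) * 0.10 / 6547 =
#' 2.06` — and cannot be moved independently; treating it as a fitted target
#' would only corrupt the exactly fittable ones. It is reported as a model
#' prediction and discussed as a structural misfit in the methods vignette.
#'
#' @param fit_all If `TRUE`, mark every target as fitted (spec of the
#'   full-set joint-feasibility check).
#' @return A data frame with columns `name`, `observed`, `tolerance`,
#'   `weight`, `fit`.
#' @export
printed_targets <- function(fit_all = FALSE) {
  t <- data.frame(
    name = c("lives_saved", "pct_reduction", "surgeries_averted",
             "anemia_averted", "lives_saved_nonsevere",
             "severe_averted_nonsevere", "optimistic_delta", "pct_gain_eff95"),
    observed = c(6547, 11, 10823, 634, 1148, 5287, 800, 10),
    tolerance = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 50, 0.5),
    stringsAsFactors = FALSE
  )
  t$weight <- (t$observed / t$tolerance)^2
  t$fit <- if (fit_all) TRUE else t$name != "pct_gain_eff95"
  t
}

#' The fixed (published) side of the calibration problem
#'
#' Region, base-case UBT assumptions, constants and uterotonic coverage —
#' everything the calibration holds at the published values.
#'
#' @return A list with elements `region`, `ubt`, `constants`, `ut_coverage`.
#' @export
fixed_config <- function() {
  list(region = region_inputs(), ubt = ubt_spec(),
       constants = model_constants(), ut_coverage = uterotonic_coverage())
}

#' Evaluate all calibration targets for a hidden-parameter set
#'
#' Runs the scenario engine once per required scenario (no-UBT baseline, base,
#' nonsevere-only, optimistic severe efficacy, and 95% nonsevere efficacy) and
#' returns the model's value for every published target. Values are
#' unrounded; rounding to the published precision is a reporting concern.
#'
#' @param hidden A [hidden_params()] object.
#' @param fixed A list as returned by [fixed_config()].
#' @return A named numeric vector over the [printed_targets()] names.
#' @examples
#' evaluate_targets(hidden_params())
#' @export
evaluate_targets <- function(hidden, fixed = fixed_config()) {
  stopifnot(inherits(hidden, "hidden_params"))
  region <- fixed$region
  constants <- fixed$constants
  cvg <- fixed$ut_coverage
  ubt_base <- fixed$ubt
  run1 <- function(ubt, filter = "all") {
    run_cascade(region, ubt, hidden, constants, population_filter = filter,
                ut_coverage = cvg)
  }
  baseline <- run1(NULL)
  base <- run1(ubt_base)
  nonsevere <- run1(ubt_base, filter = "nonsevere_only")
  optimistic <- run1(modify_ubt(ubt_base, efficacy_severe = 0.80))
  eff95 <- run1(modify_ubt(ubt_base, efficacy_nonsevere = 0.95))

  i_base <- compare_scenarios(baseline, base)
  i_ns <- compare_scenarios(baseline, nonsevere)
  i_opt <- compare_scenarios(baseline, optimistic)
  i_95 <- compare_scenarios(baseline, eff95)

  c(
    lives_saved = i_base$lives_saved,
    pct_reduction = i_base$pct_mortality_reduction,
    surgeries_averted = i_ns$surgeries_averted,
    anemia_averted = i_ns$anemia_cases_averted,
    lives_saved_nonsevere = i_ns$lives_saved,
    severe_averted_nonsevere = i_ns$severe_cases_averted,
    optimistic_delta = i_opt$lives_saved - i_base$lives_saved,
    pct_gain_eff95 = if (i_base$lives_saved > 0) {
      100 * (i_95$lives_saved - i_base$lives_saved) / i_base$lives_saved
    } else 0
  )
}

modify_ubt <- function(ubt, ...) {
  args <- list(...)
  raw <- unclass(ubt)
  raw[names(args)] <- args
  do.call(ubt_spec, raw)
}
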