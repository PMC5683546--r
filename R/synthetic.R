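# Synthetic parameter sets, ground-truth problems for calibration-recovery
# tests, and the individual-level microsimulation oracle.

#' Default sampling ranges for synthetic hidden parameters
#'
#' The package placeholders +/- 50%, clipped to \[0, 1\] for proportions —
#' wide enough to exercise calibration while staying epidemiologically sane.
#'
#' @return Named list of `c(lo, hi)` per [hidden_paths()] path.
#' @export
default_sampling_ranges <- function() {
  defaults <- c(
    uterotonic_efficacy = 0.85, presevere_fraction = 0.15,
    progression_prob = 0.30, surgery_access.home = 0.05,
    surgery_access.clinic = 0.30, surgery_access.hospital = 0.80,
    cfr_severe_no_surgery = 0.20, cfr_severe_surgery = 0.05,
    cfr_nonsevere_resolved = 0.001, nonatonic_death_load = 6000
  )
  out <- lapply(names(defaults), function(nm) {
    r <- defaults[[nm]] * c(0.5, 1.5)
    if (nm != "nonatonic_death_load") r <- pmin(r, 1)
    r
  })
  stats::setNames(out, names(defaults))
}

#' Draw a random hidden-parameter set
#'
#' Uniform draws within per-path ranges, deterministic given `seed`; the
#' constraint `cfr_severe_surgery <= cfr_severe_no_surgery` is enforced by
#' rejection.
#'
#' @param seed Integer seed.
#' @param ranges Named list of `c(lo, hi)` per path (see
#'   [default_sampling_ranges()]).
#' @return A [hidden_params()] object.
#' @export
sample_params <- function(seed, ranges = default_sampling_ranges()) {
  if (length(ranges) == 0L) stop_val("ranges must contain at least one path")
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || r[1] > r[2]) {
      stop_val("invalid range for '", nm, "'")
    }
  }
  set.seed(as.integer(seed))
  base <- hidden_params()
  repeat {
    h <- base
    for (nm in names(ranges)) {
      r <- ranges[[nm]]
      h <- hidden_set_many(h, nm, stats::runif(1, r[1], r[2]))
    }
    if (h$cfr_severe_surgery <= h$cfr_severe_no_surgery) break
  }
  # re-run constructor validation on the accepted draw
  do.call(hidden_params, lapply(unclass(h), identity))
}

#' Build a synthetic calibration problem with known ground truth
#'
#' Samples a hidden-parameter set, evaluates the full target vector under the
#' published region and UBT inputs, and records it. Calibrating against the
#' recorded targets must recover a parameter set reproducing them (the
#' recovery tests assert an objective below 1e-6).
#'
#' @param seed Integer seed.
#' @param ranges Sampling ranges, as in [sample_params()].
#' @param fixed Fixed published inputs, as from [fixed_config()].
#' @return An object of class `synthetic_problem`: `true_hidden`, `fixed`,
#'   `recorded_targets` (data frame in [printed_targets()] layout with
#'   `weight = 1` and `fit = TRUE`), `seed`.
#' @export
make_problem <- function(seed, ranges = default_sampling_ranges(),
                         fixed = fixed_config()) {
  true_hidden <- sample_params(seed, ranges)
  vals <- evaluate_targets(true_hidden, fixed)
  targets <- data.frame(name = names(vals), observed = unname(vals),
                        tolerance = 0.5, weight = 1, fit = TRUE,
                        stringsAsFactors = FALSE)
  structure(list(true_hidden = true_hidden, fixed = fixed,
                 recorded_targets = targets, seed = as.integer(seed)),
            class = "synthetic_problem")
}

#' Serialize a synthetic problem to config and targets files
#'
#' Writes the problem in the same formats real analyses use: a scenario
#' config YAML (with the ground-truth hidden parameters) and a recorded
#' targets YAML consumable by [read_targets()].
#'
#' @param problem A [make_problem()] object.
#' @param dir Output directory (created if needed).
#' @return Named character vector with the `config` and `targets` paths.
#' @export
write_problem <- function(problem, dir) {
  stopifnot(inherits(problem, "synthetic_problem"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- scenario_config(name = paste0("synthetic_seed", problem$seed),
                         region = problem$fixed$region, ubt = problem$fixed$ubt,
                         hidden = problem$true_hidden,
                         constants = problem$fixed$constants,
                         ut_coverage = problem$fixed$ut_coverage)
  config_path <- file.path(dir, "synthetic_config.yaml")
  write_scenario_config(cfg, config_path)
  targets_path <- file.path(dir, "synthetic_targets.yaml")
  write_targets(problem$recorded_targets, targets_path)
  c(config = config_path, targets = targets_path)
}

#' Read / write a calibration targets table as YAML
#'
#' @param path File path.
#' @return `read_targets` returns a targets data frame (columns `name`,
#'   `observed`, `tolerance`, `weight`, `fit`).
#' @export
read_targets <- function(path) {
  raw <- yaml::read_yaml(path)
  rows <- lapply(raw$targets, function(r) {
    data.frame(name = r$name, observed = r$observed,
               tolerance = r$tolerance %||% 0.5, weight = r$weight %||% 1,
               fit = r$fit %||% TRUE, stringsAsFactors = FALSE)
  })
  as_target_table(do.call(rbind, rows))
}

#' @rdname read_targets
#' @param targets A targets data frame.
#' @export
write_targets <- function(targets, path) {
  targets <- as_target_table(targets)
  yaml::write_yaml(list(targets = lapply(seq_len(nrow(targets)), function(i) {
    as.list(targets[i, c("name", "observed", "tolerance", "weight", "fit")])
  })), path, precision = 15L)
  invisible(path)
}

#' Individual-level microsimulation oracle
#'
#' Simulates `n_individuals` deliveries as independent sequences of binomial
#' draws through the identical event tree used by [run_cascade()] (the two
#' share one cascade walker, differing only in the split operator), scales
#' counts to the cohort size, and attaches per-field binomial standard
#' errors. Deterministic given `seed`. Serves as the brute-force check that
#' the cohort arithmetic equals the expectation of the individual-level
#' process.
#'
#' @inheritParams run_cascade
#' @param n_individuals Number of simulated deliveries (>= 0).
#' @param seed Integer seed.
#' @return An object of class `c("cascade_sim", "cascade_result")` with the
#'   scaled per-setting flows, totals, `$se` (standard errors of the scaled
#'   totals), `$n_individuals` and `$seed`.
#' @export
microsim_oracle <- function(region, ubt = NULL, hidden = hidden_params(),
                            constants = model_constants(),
                            n_individuals = 1e6, seed = 1L,
                            population_filter = c("all", "nonsevere_only"),
                            ut_coverage = uterotonic_coverage()) {
  stopifnot(inherits(region, "region_inputs"), inherits(hidden, "hidden_params"))
  population_filter <- match.arg(population_filter)
  assert_number(n_individuals, "n_individuals")
  if (n_individuals < 0) stop_val("n_individuals must be >= 0")
  n <- as.integer(round(n_individuals))
  ut_coverage <- assert_setting_map(ut_coverage, "ut_coverage")

  set.seed(as.integer(seed))
  # allocate individuals to settings by sequential binomial splits
  sh <- region$setting_shares
  n_home <- stats::rbinom(1L, n, sh[["home"]])
  rest <- n - n_home
  p_clinic <- if (sh[["clinic"]] + sh[["hospital"]] > 0) {
    sh[["clinic"]] / (sh[["clinic"]] + sh[["hospital"]])
  } else 0
  n_clinic <- stats::rbinom(1L, rest, p_clinic)
  births <- c(home = n_home, clinic = n_clinic, hospital = rest - n_clinic)

  raw <- walk_cascade(births, region, ubt, hidden, constants,
                      population_filter, ut_coverage, split_binomial)
  scale <- if (n > 0) region$live_births / n else 0

  scaled <- raw
  num_cols <- vapply(scaled, is.numeric, logical(1))
  scaled[num_cols] <- lapply(scaled[num_cols], function(v) v * scale)

  res <- build_cascade_result(scaled, hidden, constants,
                              scenario_name = if (is.null(ubt)) "baseline (sim)"
                                              else paste0(ubt$name, " (sim)"),
                              population_filter, region)
  raw_totals <- colSums(raw[TOTAL_FIELDS])
  se <- vapply(TOTAL_FIELDS, function(f) {
    if (n == 0L) return(0)
    x <- raw_totals[[f]]
    if (f == "anemia_cases") {
      constants$anemia_fraction *
        scale * sqrt(max(0, raw_totals[["severe_survivors"]] *
                           (1 - raw_totals[["severe_survivors"]] / n)))
    } else {
      scale * sqrt(max(0, x * (1 - x / n)))
    }
  }, numeric(1))
  res$se <- se
  res$n_individuals <- n
  res$seed <- as.integer(seed)
  class(res) <- c("cascade_sim", "cascade_result")
  res
}
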