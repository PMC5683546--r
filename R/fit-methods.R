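# Methods for the fitted calibration object.

#' @export
print.ubt_fit <- function(x, ...) {
  cat("Calibrated PPH cascade model (ubt_fit)\n")
  cat(sprintf("  free parameters: %d  |  fitted targets: %d of %d  |  starts: %d\n",
              length(x$free), sum(x$targets$fit), nrow(x$targets), x$n_starts))
  cat(sprintf("  objective: %.6g  |  converged (all fitted within tolerance): %s\n",
              x$objective, x$converged))
  cat("  use summary() for the target table, coef() for parameters\n")
  invisible(x)
}

#' @export
summary.ubt_fit <- function(object, ...) {
  out <- list(targets = object$targets, coef = coef(object),
              objective = object$objective, converged = object$converged,
              n_evaluations = object$n_evaluations, n_starts = object$n_starts)
  class(out) <- "summary.ubt_fit"
  out
}

#' @export
print.summary.ubt_fit <- function(x, ...) {
  cat("Calibration target fit\n")
  t <- x$targets
  t$model <- round(t$model, 2)
  t$residual <- round(t$residual, 2)
  t$within_tol <- abs(t$residual) <= t$tolerance
  print(t[, c("name", "observed", "model", "residual", "tolerance",
              "fit", "within_tol")], row.names = FALSE)
  cat(sprintf("\nobjective %.6g over %d fitted targets (%d starts, %d evaluations)\n",
              x$objective, sum(t$fit), x$n_starts, x$n_evaluations))
  cat("fitted hidden parameters:\n")
  print(round(x$coef, 5))
  invisible(x)
}

#' @export
coef.ubt_fit <- function(object, ...) {
  if (length(object$free) == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  vapply(stats::setNames(object$free, object$free),
         function(p) hidden_get(object$hidden, p), numeric(1))
}

#' @export
residuals.ubt_fit <- function(object, ...) object$residuals

#' Model predictions from a calibrated fit
#'
#' With no new data, returns the model's value for every published target at
#' the fitted parameters. Given a [scenario_config()], runs that scenario
#' (with the fitted hidden parameters substituted) against its no-UBT
#' baseline and returns the impact summary.
#'
#' @param object An `ubt_fit`.
#' @param newdata Optional [scenario_config()].
#' @param ... Unused.
#' @return Named numeric vector of target values, or an `impact_summary`.
#' @export
predict.ubt_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    return(evaluate_targets(object$hidden, object$fixed))
  }
  stopifnot(inherits(newdata, "scenario_config"))
  cf <- newdata
  cf$hidden <- object$hidden
  compare_scenarios(config_baseline(cf), run_config_cascade(cf))
}

#' Microsimulation runs at the fitted parameters
#'
#' Draws `nsim` individual-level replicates of the base scenario through the
#' same event tree as the cohort arithmetic.
#'
#' @param object An `ubt_fit`.
#' @param nsim Number of replicates.
#' @param seed Integer seed; replicate `i` uses `seed + i - 1`.
#' @param n_individuals Simulated deliveries per replicate.
#' @param ... Unused.
#' @return A list of `cascade_sim` objects (length `nsim`), or a single
#'   object when `nsim = 1`.
#' @export
simulate.ubt_fit <- function(object, nsim = 1, seed = 1L,
                             n_individuals = 1e6, ...) {
  sims <- lapply(seq_len(nsim), function(i) {
    microsim_oracle(object$fixed$region, object$fixed$ubt, object$hidden,
                    object$fixed$constants, n_individuals = n_individuals,
                    seed = as.integer(seed) + i - 1L,
                    ut_coverage = object$fixed$ut_coverage)
  })
  if (nsim == 1) sims[[1]] else sims
}

#' Four-scenario lives-saved bar chart
#'
#' Plots lives saved under the pessimistic, base, optimistic and
#' nonsevere-only scenarios at the fitted parameters.
#'
#' @param x An `ubt_fit`.
#' @param ... Passed to [graphics::barplot()].
#' @return The lives-saved vector, invisibly.
#' @export
plot.ubt_fit <- function(x, ...) {
  fx <- x$fixed
  run1 <- function(ubt, filter = "all") {
    run_cascade(fx$region, ubt, x$hidden, fx$constants,
                population_filter = filter, ut_coverage = fx$ut_coverage)
  }
  baseline <- run1(NULL)
  lives <- c(
    pessimistic = compare_scenarios(
      baseline, run1(modify_ubt(fx$ubt, efficacy_severe = 0.60)))$lives_saved,
    base = compare_scenarios(baseline, run1(fx$ubt))$lives_saved,
    optimistic = compare_scenarios(
      baseline, run1(modify_ubt(fx$ubt, efficacy_severe = 0.80)))$lives_saved,
    nonsevere_only = compare_scenarios(
      baseline, run1(fx$ubt, filter = "nonsevere_only"))$lives_saved
  )
  graphics::barplot(lives, ylab = "lives saved per year",
                    main = "UBT impact under four modelling scenarios", ...)
  invisible(lives)
}
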