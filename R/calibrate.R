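# Calibration of the hidden cascade parameters to published aggregate
# outputs: weighted least squares on relative errors, minimised by
# multi-start bounded Levenberg-Marquardt.

#' Dotted paths of the calibratable hidden parameters
#' @return Character vector of parameter paths within [hidden_params()].
#' @export
hidden_paths <- function() {
  c("uterotonic_efficacy", "presevere_fraction", "progression_prob",
    "surgery_access.home", "surgery_access.clinic", "surgery_access.hospital",
    "cfr_severe_no_surgery", "cfr_severe_surgery", "cfr_nonsevere_resolved",
    "nonatonic_death_load")
}

#' Default calibration bounds
#'
#' Proportions are bounded by \[0, 1\]; the non-atonic death load by
#' \[0, 200000\] (an order of magnitude above any plausible annual PPH death
#' toll in the region).
#'
#' @return Named list of `c(lo, hi)` per path in [hidden_paths()].
#' @export
default_bounds <- function() {
  b <- lapply(hidden_paths(), function(p) c(0, 1))
  names(b) <- hidden_paths()
  b$nonatonic_death_load <- c(0, 2e5)
  b
}

hidden_get <- function(hidden, path) get_path(unclass(hidden), path)

# Moment-matching warm starts. The cascade's aggregate responses are
# multilinear in the hidden parameters, so flow identities invert the
# targets approximately, profiled over uterotonic efficacy:
#   severe-channel sensitivity  S   = (lives - lives_nonsevere)/efficacy_severe
#   per-case fatality           d   = lives_ns/(severe_ns + surgeries_ns)
#                                     (on the cfr_surgery = cfr_no_surgery face)
#   presevere fraction          f   = S / (d * sum(failures * coverage))
#   progression / access        p,a = severe_ns, surgeries_ns / sum(G)
#   non-atonic load             from the percent-reduction denominator
# Returns a list of candidate hidden_params (possibly empty); the optimizer
# polishes the best of these alongside the other starts.
warm_starts <- function(targets, start, fixed) {
  obs <- stats::setNames(targets$observed, targets$name)[targets$fit]
  need <- c("lives_saved", "lives_saved_nonsevere", "severe_averted_nonsevere")
  if (!all(need %in% names(obs))) return(list())
  region <- fixed$region
  atonic <- region$live_births * region$setting_shares * region$pph_rate *
    region$atonic_fraction
  cvg_ut <- fixed$ut_coverage
  c_ubt <- fixed$ubt$penetration * fixed$ubt$utilization
  en <- fixed$ubt$efficacy_nonsevere
  es <- fixed$ubt$efficacy_severe
  surg_ns <- if ("surgeries_averted" %in% names(obs))
    obs[["surgeries_averted"]] else 0
  d <- obs[["lives_saved_nonsevere"]] /
    (obs[["severe_averted_nonsevere"]] + surg_ns)
  d <- min(max(d, 1e-4), 1)
  S <- (obs[["lives_saved"]] - obs[["lives_saved_nonsevere"]]) / es
  cands <- lapply(seq(0.45, 0.95, by = 0.05), function(e) {
    tryCatch({
      h <- unclass(start)
      h$uterotonic_efficacy <- e
      failures <- atonic * (1 - cvg_ut * e)
      sum_fc <- sum(failures * c_ubt)
      f <- min(max(S / (d * sum_fc), 0.01), 0.95)
      sum_g <- (1 - f) * sum_fc * en
      h$presevere_fraction <- f
      h$progression_prob <-
        min(max(obs[["severe_averted_nonsevere"]] / sum_g, 1e-4), 1)
      if (surg_ns > 0) {
        a <- min(max(surg_ns / sum_g, 1e-4), 1)
        h$surgery_access[c("clinic", "hospital")] <- a
      }
      h$surgery_access[["home"]] <- 0
      h$cfr_severe_no_surgery <- d
      h$cfr_severe_surgery <- d
      h$cfr_nonsevere_resolved <- 5e-4
      h <- structure(h, class = "hidden_params")
      if ("pct_reduction" %in% names(obs)) {
        target_deaths <- 100 * obs[["lives_saved"]] / obs[["pct_reduction"]]
        h$nonatonic_death_load <- 0
        base_deaths <- run_cascade(region, NULL, h, fixed$constants,
                                   ut_coverage = cvg_ut)$totals$deaths
        h$nonatonic_death_load <- max(0, target_deaths - base_deaths)
      }
      h
    }, error = function(e) NULL)
  })
  Filter(Negate(is.null), cands)
}

hidden_set_many <- function(hidden, paths, values) {
  raw <- unclass(hidden)
  for (i in seq_along(paths)) raw <- set_path(raw, paths[[i]], values[[i]])
  # assembled without constructor checks: the optimizer enforces the CFR
  # ordering through a penalty residual instead of hard failures
  structure(raw, class = "hidden_params")
}

as_target_table <- function(targets) {
  stopifnot(is.data.frame(targets), all(c("name", "observed") %in% names(targets)))
  if (is.null(targets$tolerance)) targets$tolerance <- 0.5
  if (is.null(targets$weight)) targets$weight <- 1
  if (is.null(targets$fit)) targets$fit <- TRUE
  if (any(targets$tolerance <= 0)) stop_val("target tolerances must be > 0")
  if (any(targets$weight <= 0)) stop_val("target weights must be > 0")
  if (any(targets$observed == 0)) {
    stop_val("targets with observed value 0 are not supported by the ",
             "relative-error objective")
  }
  targets
}

#' Calibrate the hidden cascade parameters to aggregate targets
#'
#' Estimates the unpublished cascade parameters by minimising the weighted
#' squared relative-error objective
#' `sum(weight * ((model - observed) / observed)^2)` over the free parameter
#' paths, with bounds, using Levenberg-Marquardt least squares
#' ([minpack.lm::nls.lm]) from `n_starts` starting points (the supplied
#' `start` plus Latin-hypercube draws over the bounds). Deterministic given
#' `seed`. Rows of `targets` with `fit = FALSE` are excluded from the
#' objective but their residuals are still evaluated and reported.
#'
#' @param targets Data frame with columns `name`, `observed` and optionally
#'   `tolerance` (> 0, default 0.5), `weight` (> 0, default 1) and `fit`
#'   (logical, default `TRUE`). Names must be a subset of the
#'   [printed_targets()] names.
#' @param free Character vector of parameter paths to estimate (subset of
#'   [hidden_paths()]); if empty, the start values are returned unchanged
#'   with the residuals of that model.
#' @param bounds Named list of `c(lo, hi)` per free path.
#' @param seed Integer seed for the multi-start design.
#' @param n_starts Number of optimizer starts.
#' @param start A [hidden_params()] object used as the first start and as the
#'   value of non-free parameters.
#' @param fixed Fixed published inputs, as from [fixed_config()].
#' @param control Passed to [minpack.lm::nls.lm.control].
#' @return An object of class `ubt_fit` with components `hidden` (fitted
#'   [hidden_params()]), `targets` (table with model values and residuals),
#'   `residuals`, `objective`, `converged` (all fitted residuals within
#'   tolerance), `n_evaluations`, `start_objectives`, plus the call inputs.
#'   Supported methods: `print`, `summary`, `coef`, `residuals`, `predict`,
#'   `simulate`, `plot`.
#' @examples
#' \donttest{
#' fit <- ubt_calibrate(n_starts = 4, seed = 1)
#' summary(fit)
#' }
#' @export
ubt_calibrate <- function(targets = printed_targets(),
                          free = hidden_paths(),
                          bounds = default_bounds(),
                          seed = 1L,
                          n_starts = 32L,
                          start = hidden_params(),
                          fixed = fixed_config(),
                          control = minpack.lm::nls.lm.control(
                            maxiter = 500, ftol = 1e-14, ptol = 1e-14)) {
  targets <- as_target_table(targets)
  if (!any(targets$fit)) stop_val("at least one target must have fit = TRUE")
  unknown <- setdiff(targets$name, names(evaluate_targets(start, fixed)))
  if (length(unknown)) stop_val("unknown target name(s): ",
                                paste(unknown, collapse = ", "))
  stopifnot(inherits(start, "hidden_params"))
  free <- unique(free)
  for (p in free) hidden_get(start, p) # errors if a path does not resolve
  lo <- hi <- numeric(length(free))
  for (i in seq_along(free)) {
    b <- bounds[[free[i]]]
    if (is.null(b) || length(b) != 2L) {
      stop_val("missing bounds for free parameter '", free[i], "'")
    }
    if (b[1] > b[2]) stop_val("infeasible bounds for '", free[i],
                              "': lo > hi")
    lo[i] <- b[1]; hi[i] <- b[2]
  }

  fit_rows <- targets[targets$fit, , drop = FALSE]
  sw <- sqrt(fit_rows$weight)
  n_eval <- 0L
  # Levenberg-Marquardt needs >= as many residuals as parameters; an
  # under-determined problem (expected here) is padded with structural zeros.
  n_pad <- max(0L, length(free) - nrow(fit_rows) - 1L)
  resid_fn <- function(par) {
    n_eval <<- n_eval + 1L
    h <- hidden_set_many(start, free, par)
    m <- evaluate_targets(h, fixed)[fit_rows$name]
    r <- sw * (m - fit_rows$observed) / fit_rows$observed
    # soft constraint: surgical case fatality may not exceed non-surgical
    pen <- 1e3 * max(0, h$cfr_severe_surgery - h$cfr_severe_no_surgery)
    c(r, pen, numeric(n_pad))
  }

  if (length(free) == 0L) {
    best_par <- numeric(0)
    start_objs <- sum(resid_fn(numeric(0))^2)
  } else {
    set.seed(as.integer(seed))
    starts <- matrix(vapply(free, function(p) hidden_get(start, p),
                            numeric(1)), nrow = 1)
    ws <- warm_starts(targets, start, fixed)
    if (length(ws)) {
      ws_pars <- do.call(rbind, lapply(ws, function(h) {
        vapply(free, function(p) hidden_get(h, p), numeric(1))
      }))
      ws_obj <- apply(ws_pars, 1, function(par) sum(resid_fn(par)^2))
      keep <- order(ws_obj)[seq_len(min(2L, nrow(ws_pars)))]
      starts <- rbind(starts, ws_pars[keep, , drop = FALSE])
    }
    n_lhs <- n_starts - nrow(starts)
    if (n_lhs > 0L) {
      u <- lhs::randomLHS(n_lhs, length(free))
      extra <- sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
      starts <- rbind(starts, extra)
    }
    fits <- vector("list", nrow(starts))
    for (k in seq_len(nrow(starts))) {
      fits[[k]] <- minpack.lm::nls.lm(
        par = pmin(pmax(starts[k, ], lo), hi),
        lower = lo, upper = hi, fn = resid_fn, control = control)
    }
    start_objs <- vapply(fits, function(f) sum(resid_fn_value(f)^2), numeric(1))
    best <- which.min(start_objs)
    best_par <- fits[[best]]$par
  }

  hidden_fit <- hidden_set_many(start, free, best_par)
  model <- evaluate_targets(hidden_fit, fixed)[targets$name]
  targets$model <- unname(model)
  targets$residual <- targets$model - targets$observed
  fit_mask <- targets$fit
  objective <- sum(targets$weight[fit_mask] *
                   (targets$residual[fit_mask] / targets$observed[fit_mask])^2)
  converged <- all(abs(targets$residual[fit_mask]) <= targets$tolerance[fit_mask])
  res <- stats::setNames(targets$residual, targets$name)

  structure(
    list(hidden = hidden_fit, start = start, free = free,
         bounds = bounds[free], targets = targets, residuals = res,
         objective = objective, converged = converged,
         n_evaluations = n_eval,
         start_objectives = start_objs,
         n_starts = length(start_objs),
         seed = as.integer(seed), fixed = fixed),
    class = "ubt_fit"
  )
}

# deviance of a converged nls.lm fit (residual vector is stored in $fvec)
resid_fn_value <- function(fit) fit$fvec

#' Profile a calibrated parameter for identifiability
#'
#' Fixes one calibrated parameter at each grid value, re-optimizes the
#' remaining free parameters (warm-started at the fitted values), and records
#' the best objective. A flat profile — objective range below 10% of the
#' profile minimum (with a small absolute floor) — flags the parameter as
#' non-identifiable from the fitted targets.
#'
#' @param fit An `ubt_fit` object.
#' @param path One of `fit$free`.
#' @param grid Numeric values within the parameter's bounds.
#' @param n_starts Optimizer starts per grid point (warm start plus
#'   Latin-hypercube draws).
#' @return A data frame with columns `value` and `objective`; attributes
#'   `identifiable` (logical) and `path`.
#' @export
identifiability_scan <- function(fit, path, grid, n_starts = 4L) {
  stopifnot(inherits(fit, "ubt_fit"))
  if (!path %in% fit$free) {
    stop_val("'", path, "' is not among the calibrated parameters")
  }
  b <- fit$bounds[[path]]
  if (any(grid < b[1] - 1e-12) || any(grid > b[2] + 1e-12)) {
    stop_val("grid for '", path, "' lies outside its bounds [",
             b[1], ", ", b[2], "]")
  }
  rest <- setdiff(fit$free, path)
  objs <- vapply(grid, function(v) {
    start <- hidden_set_many(fit$hidden, path, v)
    sub <- ubt_calibrate(targets = fit$targets[, c("name", "observed",
                                                   "tolerance", "weight", "fit")],
                         free = rest, bounds = fit$bounds, seed = fit$seed,
                         n_starts = n_starts, start = start, fixed = fit$fixed)
    sub$objective
  }, numeric(1))
  out <- data.frame(value = grid, objective = objs)
  rng <- max(objs) - min(objs)
  attr(out, "identifiable") <- rng >= 0.1 * min(objs) + 1e-9
  attr(out, "path") <- path
  out
}
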