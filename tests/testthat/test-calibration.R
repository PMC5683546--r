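test_that("a deathless parameter set evaluates all mortality targets to zero", {
  h <- hidden_params(cfr_severe_no_surgery = 0, cfr_severe_surgery = 0,
                     cfr_nonsevere_resolved = 0, nonatonic_death_load = 0)
  v <- evaluate_targets(h)
  expect_equal(unname(v["lives_saved"]), 0)
  expect_equal(unname(v["pct_reduction"]), 0)
  expect_equal(unname(v["lives_saved_nonsevere"]), 0)
  expect_equal(unname(v["pct_gain_eff95"]), 0)
  # morbidity channels are still active
  expect_gt(unname(v["surgeries_averted"]), 0)
  expect_gt(unname(v["severe_averted_nonsevere"]), 0)
})

test_that("the stored objective is recomputable from the residuals", {
  fit <- quick_calibrate(seed = 3, n_starts = 2)
  t <- fit$targets
  m <- t$fit
  recomputed <- sum(t$weight[m] * (t$residual[m] / t$observed[m])^2)
  expect_lt(abs(recomputed - fit$objective), 1e-9)
  # residuals recompute from the fitted parameters
  v <- evaluate_targets(fit$hidden)[t$name]
  expect_lt(max(abs(unname(v - t$observed) - t$residual)), 1e-9)
})

test_that("calibration is bit-identical across reruns with the same seed", {
  f1 <- quick_calibrate(seed = 7, n_starts = 3)
  f2 <- quick_calibrate(seed = 7, n_starts = 3)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$objective, f2$objective)
  expect_identical(f1$targets, f2$targets)
})

test_that("an empty free list returns the start unchanged with its residuals", {
  start <- hidden_params()
  fit <- ubt_calibrate(free = character(0), start = start)
  expect_identical(fit$hidden, start)
  expect_length(coef(fit), 0)
  v <- evaluate_targets(start)
  expect_equal(unname(fit$residuals), unname(v[fit$targets$name] -
                                               fit$targets$observed))
})

test_that("calibration input validation rejects bad problems", {
  t <- printed_targets()
  expect_error(ubt_calibrate(targets = t,
                             bounds = list(uterotonic_efficacy = c(0.9, 0.1)),
                             free = "uterotonic_efficacy"), "infeasible bounds")
  t0 <- t; t0$fit <- FALSE
  expect_error(ubt_calibrate(targets = t0), "at least one target")
  tneg <- t; tneg$weight[1] <- 0
  expect_error(ubt_calibrate(targets = tneg), "weights")
  expect_error(ubt_calibrate(free = "no.such.path"), "no.such.path")
})

test_that("calibration recovers synthetic ground-truth target vectors", {
  for (s in c(21, 22)) {
    pr <- make_problem(s)
    fit <- quick_calibrate(targets = pr$recorded_targets, seed = s, n_starts = 4)
    expect_lt(fit$objective, 1e-6)
    expect_true(fit$converged)
  }
})

test_that("profiling an inert parameter flags it as non-identifiable", {
  # with no UBT at home and the percent-reduction target excluded, home
  # surgical access enters no fitted quantity
  t <- printed_targets()
  t <- t[t$name != "pct_reduction", ]
  fit <- quick_calibrate(targets = t, seed = 5, n_starts = 4)
  scan <- identifiability_scan(fit, "surgery_access.home",
                               grid = c(0.1, 0.3, 0.5), n_starts = 1)
  expect_false(attr(scan, "identifiable"))
  expect_lt(max(scan$objective) - min(scan$objective),
            0.1 * min(scan$objective) + 1e-9)
})

test_that("profiling a synthetic problem dips at the ground truth", {
  pr <- make_problem(31)
  truth <- pr$true_hidden$uterotonic_efficacy
  fit <- quick_calibrate(targets = pr$recorded_targets, seed = 31, n_starts = 4)
  grid <- sort(unique(c(truth, seq(0.5, 0.95, by = 0.15))))
  scan <- identifiability_scan(fit, "uterotonic_efficacy", grid, n_starts = 2)
  # the profile evaluated at the truth must be (near-)minimal
  expect_lt(scan$objective[scan$value == truth],
            min(scan$objective) + 1e-6 + 0.1 * min(scan$objective))
  expect_error(identifiability_scan(fit, "uterotonic_efficacy", grid = c(-1, 2)),
               "bounds")
  expect_error(identifiability_scan(fit, "constants.never_fit", 0.5),
               "not among")
})
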