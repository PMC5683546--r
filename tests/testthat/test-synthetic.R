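test_that("parameter sampling is deterministic and respects its ranges", {
  expect_identical(sample_params(42), sample_params(42))
  expect_false(identical(unclass(sample_params(1)), unclass(sample_params(2))))

  ranges <- default_sampling_ranges()
  draws <- lapply(1:200, sample_params)
  for (path in names(ranges)) {
    vals <- vapply(draws, function(h) ubtimpact:::get_path(unclass(h), path), numeric(1))
    expect_true(all(vals >= ranges[[path]][1] - 1e-12))
    expect_true(all(vals <= ranges[[path]][2] + 1e-12))
  }
  ok <- vapply(draws, function(h) {
    h$cfr_severe_surgery <= h$cfr_severe_no_surgery
  }, logical(1))
  expect_true(all(ok))
})

test_that("degenerate ranges pin parameters and empty ranges error", {
  r <- default_sampling_ranges()
  r$progression_prob <- c(0.2, 0.2)
  expect_equal(sample_params(9, r)$progression_prob, 0.2)
  expect_error(sample_params(1, list()), "at least one")
  expect_error(sample_params(1, list(progression_prob = c(0.5, 0.1))), "range")
})

test_that("synthetic problems record a self-consistent target vector", {
  pr <- make_problem(17)
  v <- evaluate_targets(pr$true_hidden, pr$fixed)
  expect_lt(max(abs(v[pr$recorded_targets$name] - pr$recorded_targets$observed)),
            1e-9)
  expect_false(identical(make_problem(1)$true_hidden, make_problem(2)$true_hidden))
})

test_that("synthetic problems round-trip through config and targets files", {
  pr <- make_problem(23)
  dir <- withr::local_tempdir()
  paths <- write_problem(pr, dir)
  cf <- read_scenario_config(paths[["config"]])
  expect_equal(unclass(cf$hidden), unclass(pr$true_hidden), tolerance = 1e-12)
  t <- read_targets(paths[["targets"]])
  expect_equal(t$observed, pr$recorded_targets$observed, tolerance = 1e-12)
})

test_that("the microsimulation shares the cascade's branch structure", {
  # with every branch probability at 0 or 1 the binomial draws are
  # deterministic, so the individual-level walk must equal the cohort
  # arithmetic exactly
  r <- region_inputs(live_births = 1000,
                     setting_shares = c(home = 0, clinic = 0, hospital = 1),
                     pph_rate = c(home = 0, clinic = 0, hospital = 1),
                     atonic_fraction = 1)
  u <- ubt_spec(penetration = c(home = 0, clinic = 0, hospital = 1),
                utilization = c(home = 0, clinic = 0, hospital = 1),
                efficacy_nonsevere = 1, efficacy_severe = 0)
  h <- hidden_params(uterotonic_efficacy = 0, presevere_fraction = 1,
                     progression_prob = 1,
                     surgery_access = c(home = 0, clinic = 0, hospital = 1),
                     cfr_severe_no_surgery = 1, cfr_severe_surgery = 1,
                     cfr_nonsevere_resolved = 0, nonatonic_death_load = 0)
  det <- run_cascade(r, u, h, ut_coverage = c(home = 0, clinic = 0, hospital = 1))
  sim <- microsim_oracle(r, u, h, n_individuals = 1000, seed = 1,
                         ut_coverage = c(home = 0, clinic = 0, hospital = 1))
  expect_cascade_equal(det, sim)
  expect_true(all(sim$se == 0))
})

test_that("microsim handles the empty cohort and repeats under a fixed seed", {
  r <- region_inputs()
  sim0 <- microsim_oracle(r, ubt_spec(), hidden_params(), n_individuals = 0,
                          seed = 1)
  expect_true(all(unlist(sim0$totals[ubtimpact:::TOTAL_FIELDS]) == 0))
  expect_true(all(sim0$se == 0))
  expect_error(microsim_oracle(r, n_individuals = -1), "n_individuals")

  a <- microsim_oracle(r, ubt_spec(), hidden_params(), n_individuals = 1e5,
                       seed = 99)
  b <- microsim_oracle(r, ubt_spec(), hidden_params(), n_individuals = 1e5,
                       seed = 99)
  expect_identical(a$totals, b$totals)
  expect_identical(a$se, b$se)
})

test_that("cohort arithmetic matches the oracle within three standard errors", {
  fields <- c("deaths", "surgeries", "severe_cases_total", "resolved_by_ubt",
              "progressed_to_severe")
  for (s in 1:3) {
    h <- sample_params(300 + s)
    det <- run_cascade(table1_region(), ubt_spec(), h)
    sim <- microsim_oracle(table1_region(), ubt_spec(), h,
                           n_individuals = 5e5, seed = s)
    for (f in fields) {
      expect_lt(abs(sim$totals[[f]] - det$totals[[f]]), 3 * sim$se[[f]])
    }
  }
})

test_that("oracle standard errors shrink like one over root n", {
  h <- hidden_params()
  se_n <- microsim_oracle(table1_region(), ubt_spec(), h,
                          n_individuals = 2.5e5, seed = 8)$se[["deaths"]]
  se_4n <- microsim_oracle(table1_region(), ubt_spec(), h,
                           n_individuals = 1e6, seed = 8)$se[["deaths"]]
  expect_lt(abs(se_n / se_4n - 2), 0.4) # halving within 20%
})
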