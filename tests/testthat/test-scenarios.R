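test_that("comparing a result with itself gives all-zero impact", {
  res <- run_cascade(table1_region(), ubt_spec(), hidden_params())
  imp <- compare_scenarios(res, res)
  expect_equal(imp$lives_saved, 0)
  expect_equal(imp$pct_mortality_reduction, 0)
  expect_equal(imp$surgeries_averted, 0)
  expect_equal(imp$severe_cases_averted, 0)
  expect_equal(imp$anemia_cases_averted, 0)
})

test_that("swapping comparison arguments negates every delta", {
  h <- hidden_params()
  a <- run_cascade(table1_region(), NULL, h)
  b <- run_cascade(table1_region(), ubt_spec(), h)
  ab <- compare_scenarios(a, b)
  ba <- compare_scenarios(b, a)
  for (f in c("lives_saved", "surgeries_averted", "severe_cases_averted",
              "anemia_cases_averted")) {
    expect_equal(ab[[f]], -ba[[f]])
  }
})

test_that("results from different regions refuse to be compared", {
  a <- run_cascade(table1_region(), NULL, hidden_params())
  b <- run_cascade(region_inputs(live_births = 1e6), ubt_spec(), hidden_params())
  expect_error(compare_scenarios(a, b), "region")
})

test_that("scenario sets run against a shared baseline in input order", {
  cfgs <- list(
    scenario_config(name = "pessimistic", ubt = ubt_spec(efficacy_severe = 0.60)),
    scenario_config(name = "base"),
    scenario_config(name = "optimistic", ubt = ubt_spec(efficacy_severe = 0.80))
  )
  tab <- run_scenario_set(cfgs)
  expect_equal(tab$scenario, c("pessimistic", "base", "optimistic"))
  # lives saved ordered ascending in severe efficacy 0.60 < 0.70 < 0.80
  expect_true(all(diff(tab$lives_saved) > 0))

  expect_equal(nrow(run_scenario_set(list())), 0L)

  single <- run_scenario_set(cfgs[2])
  direct <- compare_scenarios(
    run_cascade(table1_region(), NULL, hidden_params()),
    run_cascade(table1_region(), ubt_spec(), hidden_params(),
                scenario_name = "base"))
  expect_equal(single$lives_saved, direct$lives_saved)
  expect_equal(single$surgeries_averted, direct$surgeries_averted)

  expect_error(run_scenario_set(list(cfgs[[2]], cfgs[[2]])), "duplicate")
})

test_that("restricting the UBT to nonsevere cases saves fewer lives", {
  cfgs <- list(scenario_config(name = "base"),
               scenario_config(name = "nonsevere_only", filter = "nonsevere_only"))
  tab <- run_scenario_set(cfgs)
  expect_lt(tab$lives_saved[2], tab$lives_saved[1])
})

test_that("one-way sensitivity sweeps one parameter and reports deltas", {
  cf <- scenario_config()
  tab <- one_way_sensitivity(cf, "ubt.efficacy_severe", c(0.60, 0.70, 0.80))
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$delta_vs_base[2], 0) # base value included in the sweep
  expect_true(tab$delta_vs_base[1] < 0 && tab$delta_vs_base[3] > 0)
  # lives saved affine in the tested value
  fitln <- stats::lm(lives_saved ~ tested_value, data = tab)
  expect_lt(max(abs(stats::residuals(fitln))), 1e-9)

  expect_equal(nrow(one_way_sensitivity(cf, "ubt.efficacy_severe", numeric(0))), 0L)
  expect_error(one_way_sensitivity(cf, "ubt.no_such_field", 0.5), "no_such_field")
})

test_that("hidden-parameter sweeps keep baseline and scenario consistent", {
  cf <- scenario_config()
  tab <- one_way_sensitivity(cf, "hidden.uterotonic_efficacy", c(0.6, 0.85))
  expect_equal(tab$lives_saved[2] - tab$lives_saved[1], tab$delta_vs_base[2] -
                 tab$delta_vs_base[1])
  expect_true(all(is.finite(tab$lives_saved)))
})
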