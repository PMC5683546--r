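test_that("per-setting flows conserve the entering caseload", {
  # terminal states partition the atonic cases entering each setting
  set.seed(11)
  for (i in 1:10) {
    h <- sample_params(seed = 100 + i)
    u <- ubt_spec(efficacy_severe = runif(1), efficacy_nonsevere = runif(1))
    res <- run_cascade(table1_region(), u, h)
    s <- res$settings
    outflow <- s$resolved_by_uterotonic + s$resolved_by_ubt +
      s$nonsevere_refractory + s$severe_unresolved
    expect_lt(max(abs(outflow - s$cases_entering)), 1e-9 * max(s$cases_entering))
    # survivors + deaths = cases entering
    expect_true(all(s$deaths >= 0))
    expect_lte(res$totals$deaths, res$totals$pph_cases)
  }
})

test_that("an inert UBT reproduces the baseline field-by-field", {
  h <- hidden_params()
  baseline <- run_cascade(table1_region(), NULL, h)
  for (u in list(
    ubt_spec(penetration = c(home = 0, clinic = 0, hospital = 0)),
    ubt_spec(utilization = c(home = 0, clinic = 0, hospital = 0)),
    ubt_spec(efficacy_nonsevere = 0, efficacy_severe = 0))) {
    expect_cascade_equal(run_cascade(table1_region(), u, h), baseline)
  }
})

test_that("perfect first-line UBT rescue leaves no progression where covered", {
  u <- ubt_spec(penetration = c(home = 1, clinic = 1, hospital = 1),
                utilization = c(home = 1, clinic = 1, hospital = 1),
                efficacy_nonsevere = 1)
  h <- hidden_params(presevere_fraction = 0, progression_prob = 0.4)
  res <- run_cascade(table1_region(), u, h)
  prog <- res$settings$progressed_to_severe
  names(prog) <- res$settings$setting
  expect_equal(unname(prog[c("clinic", "hospital")]), c(0, 0))
})

test_that("deaths fall and UBT resolutions rise along each coverage dial", {
  h <- hidden_params()
  grid <- seq(0.1, 0.9, length.out = 5)
  dials <- list(
    pen = function(v) ubt_spec(penetration = c(home = 0, clinic = v, hospital = v)),
    util = function(v) ubt_spec(utilization = c(home = 0, clinic = v, hospital = v)),
    eff_ns = function(v) ubt_spec(efficacy_nonsevere = v),
    eff_sev = function(v) ubt_spec(efficacy_severe = v)
  )
  for (dial in dials) {
    runs <- lapply(grid, function(v) run_cascade(table1_region(), dial(v), h))
    deaths <- vapply(runs, function(r) r$totals$deaths, numeric(1))
    resolved <- vapply(runs, function(r) r$totals$resolved_by_ubt, numeric(1))
    expect_true(all(diff(deaths) <= 1e-9))
    expect_true(all(diff(resolved) >= -1e-9))
  }
})

test_that("deaths averted in the severe stratum are affine in severe efficacy", {
  h <- hidden_params()
  baseline <- run_cascade(table1_region(), NULL, h)$totals$total_pph_deaths
  eff <- c(0.2, 0.5, 0.9)
  lives <- vapply(eff, function(v) {
    baseline - run_cascade(table1_region(), ubt_spec(efficacy_severe = v),
                           h)$totals$total_pph_deaths
  }, numeric(1))
  fitln <- stats::lm(lives ~ eff)
  expect_lt(max(abs(stats::residuals(fitln))), 1e-9)
})

test_that("invalid filters and probabilities are rejected", {
  expect_error(run_cascade(table1_region(), ubt_spec(), hidden_params(),
                           population_filter = "severe_only"))
  expect_error(run_cascade(table1_region(), ubt_spec(), hidden_params(),
                           ut_coverage = c(home = -0.1, clinic = 0.6, hospital = 0.8)),
               "ut_coverage")
})

test_that("the nonsevere-only filter only silences the severe stratum", {
  h <- hidden_params()
  full <- run_cascade(table1_region(), ubt_spec(), h)
  ns <- run_cascade(table1_region(), ubt_spec(), h,
                    population_filter = "nonsevere_only")
  expect_true(all(ns$settings$resolved_by_ubt_severe == 0))
  expect_equal(ns$settings$resolved_by_ubt_nonsevere,
               full$settings$resolved_by_ubt_nonsevere)
  # withholding the device above the threshold matches zero severe efficacy
  es0 <- run_cascade(table1_region(), ubt_spec(efficacy_severe = 0), h)
  expect_cascade_equal(ns, es0)
})
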