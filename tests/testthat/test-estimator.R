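base_params <- prophylaxis_params()

test_that("risk adjustment applies efficacy, harm and the probability cap", {
  # untreated risks pass through unchanged
  expect_equal(
    adjust_risks(0.02, 0.005, FALSE, base_params),
    tibble::tibble(p_vte = 0.02, p_bleed = 0.005)
  )
  # treated: VTE down by 52%, bleeding up by 37%
  adj <- adjust_risks(0.02, 0.005, TRUE, base_params)
  expect_equal(adj$p_vte, 0.0096)
  expect_equal(adj$p_bleed, 0.00685)
  # the maximum observed bleeding risk times the maximum harm exceeds 1: capped
  hi <- adjust_risks(0.10, 0.786, TRUE, prophylaxis_params(0.52, 1.92))
  expect_equal(hi$p_bleed, 1)
})

test_that("expected events match the closed form on identical patients", {
  co <- make_cohort(rep(0.01, 1000), rep(0.002, 1000))
  out <- expected_events(co, rep(TRUE, 1000), base_params, name = "all_treated")
  expect_equal(out$vte_per_1000, 4.8)
  expect_equal(out$bleed_per_1000, 2.74)
  expect_equal(out$total_per_1000, 7.54)
  expect_equal(out$prophylaxis_per_100, 100)
})

test_that("no prophylaxis reproduces the raw mean risks; totals are additive", {
  co <- random_cohort(400, seed = 21)
  out <- expected_events(co, rep(FALSE, 400), base_params, name = "none")
  expect_equal(out$vte_per_1000, 1000 * mean(co$p_vte))
  expect_equal(out$bleed_per_1000, 1000 * mean(co$p_bleed))
  for (s in STRATEGY_NAMES) {
    o <- expected_events(co, assign_prophylaxis(co, s, base_params), base_params, s)
    expect_equal(o$total_per_1000, o$vte_per_1000 + o$bleed_per_1000)
  }
  expect_error(expected_events(co, rep(TRUE, 3), base_params),
    class = "vteprophy_config_error"
  )
})

test_that("expected events agree with the per-patient loop oracle", {
  co <- random_cohort(250, seed = 5)
  for (s in c("physicians", "cc_minimize_events", "near_universal")) {
    ind <- assign_prophylaxis(co, s, base_params)
    out <- expected_events(co, ind, base_params, s)
    oracle <- brute_expected_rates(co, ind, 0.52, 1.37)
    expect_equal(out$vte_per_1000, unname(oracle["vte_per_1000"]))
    expect_equal(out$bleed_per_1000, unname(oracle["bleed_per_1000"]))
  }
})

test_that("treating one more patient never raises VTE nor lowers bleeding", {
  co <- random_cohort(200, seed = 8)
  ind <- assign_prophylaxis(co, "physicians", base_params)
  base_out <- expected_events(co, ind, base_params)
  set.seed(80)
  for (i in sample(which(!ind), 10)) {
    flipped <- ind
    flipped[i] <- TRUE
    out <- expected_events(co, flipped, base_params)
    expect_lte(out$vte_per_1000, base_out$vte_per_1000)
    expect_gte(out$bleed_per_1000, base_out$bleed_per_1000)
  }
})

test_that("a null treatment effect reproduces the untreated outcome", {
  co <- random_cohort(300, seed = 13)
  null_params <- prophylaxis_params(efficacy_rrr = 1e-15, harm_rr = 1)
  none <- expected_events(co, rep(FALSE, 300), null_params, "none")
  for (s in setdiff(STRATEGY_NAMES, "no_prophylaxis")) {
    ind <- assign_prophylaxis(co, s, null_params)
    out <- expected_events(co, ind, null_params, s)
    expect_equal(out$vte_per_1000, none$vte_per_1000, tolerance = 1e-12)
    expect_equal(out$bleed_per_1000, none$bleed_per_1000, tolerance = 1e-12)
  }
})

test_that("simulation is seed-reproducible and vanishes with vanishing risk", {
  co <- make_cohort(rep(1e-9, 50), rep(1e-9, 50))
  sim <- simulate_events(co, rep(FALSE, 50), base_params, n_reps = 10, seed = 4)
  expect_equal(sum(sim$vte_counts), 0)
  expect_equal(sum(sim$bleed_counts), 0)
  co2 <- random_cohort(100, seed = 2)
  ind <- assign_prophylaxis(co2, "near_universal", base_params)
  s1 <- simulate_events(co2, ind, base_params, n_reps = 200, seed = 7)
  s2 <- simulate_events(co2, ind, base_params, n_reps = 200, seed = 7)
  expect_identical(s1$vte_counts, s2$vte_counts)
  expect_identical(s1$bleed_counts, s2$bleed_counts)
  # and the caller's RNG stream is not disturbed
  set.seed(1)
  before <- rnorm(1)
  set.seed(1)
  invisible(simulate_events(co2, ind, base_params, n_reps = 10, seed = 99))
  expect_identical(rnorm(1), before)
})

test_that("the Monte-Carlo mean matches the analytic expectation (law of large numbers)", {
  co <- make_cohort(rep(0.01, 1000), rep(0.002, 1000))
  sim <- simulate_events(co, rep(TRUE, 1000), base_params, n_reps = 10000, seed = 31)
  expect_lt(abs(sim$mean_vte_per_1000 - 4.8), 3 * sim$se_vte_per_1000)
  expect_lt(abs(sim$mean_bleed_per_1000 - 2.74), 3 * sim$se_bleed_per_1000)
})

test_that("simulation agrees with the analytic estimator across strategies", {
  co <- generate_cohort(synth_config(n = 500L, seed = 17L))
  for (s in c("guidelines", "cc_minimize_events", "physicians")) {
    ind <- assign_prophylaxis(co, s, base_params)
    out <- expected_events(co, ind, base_params, s)
    sim <- simulate_events(co, ind, base_params, n_reps = 2000, seed = 23)
    expect_lt(abs(sim$mean_vte_per_1000 - out$vte_per_1000), 3 * sim$se_vte_per_1000)
    expect_lt(
      abs(sim$mean_bleed_per_1000 - out$bleed_per_1000),
      3 * sim$se_bleed_per_1000
    )
  }
})
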