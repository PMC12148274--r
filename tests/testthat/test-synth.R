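test_that("log-normal moment matching recovers location and scale in closed form", {
  par <- derive_lognormal_params(0.0126, 0.0074)
  expect_equal(par$meanlog, log(0.0074))
  expect_equal(par$meanlog, -4.906275, tolerance = 1e-6)
  expect_equal(par$sdlog, 1.031714, tolerance = 1e-6)
  expect_equal(derive_lognormal_params(0.0052, 0.0021)$sdlog, 1.346641,
    tolerance = 1e-6
  )
  # algebraic identity: mean = median * exp(1/2) gives unit log-scale
  expect_equal(derive_lognormal_params(0.01 * exp(0.5), 0.01)$sdlog, 1)
  expect_error(derive_lognormal_params(0.005, 0.007),
    class = "vteprophy_config_error"
  )
})

test_that("the matched law has the requested mean and median (simulation check)", {
  par <- derive_lognormal_params(0.0126, 0.0074)
  set.seed(1234)
  draws <- stats::rlnorm(1e6, par$meanlog, par$sdlog)
  expect_equal(mean(draws), 0.0126, tolerance = 0.01)
  expect_equal(median(draws), 0.0074, tolerance = 0.01)
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_cohort(synth_config(n = 10L, seed = 5L))
  b <- generate_cohort(synth_config(n = 10L, seed = 5L))
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  c <- generate_cohort(synth_config(n = 10L, seed = 6L))
  expect_false(identical(a$p_vte, c$p_vte))
})

test_that("the default cohort reproduces the target marginals and prescribing", {
  co <- generate_cohort(synth_config())
  s <- summarize_cohort(co)
  expect_equal(s$n, 46025)
  expect_gt(s$vte_median, 0.006)
  expect_lt(s$vte_median, 0.009)
  expect_gt(s$vte_mean, 0.010)
  expect_lt(s$vte_mean, 0.016)
  expect_equal(s$bleed_median, 0.0021, tolerance = 0.05)
  expect_equal(s$bleed_mean, 0.0052, tolerance = 0.05)
  expect_lt(abs(s$ppx_rate - 0.617), 0.03)
  expect_equal(s$vte_min, 0.0031)
  expect_lte(s$vte_max, 0.453)
  expect_gte(s$bleed_min, 0.00017)
})

test_that("prescribing rises with VTE risk but stays near-flat in bleeding risk", {
  co <- generate_cohort(synth_config())
  rep <- quantile_prescribing_report(co, 10)
  overall <- 100 * mean(co$physician_prophylaxis)
  vte <- rep[rep$axis == "vte" & rep$n > 0, ]
  expect_gte(
    vte$ppx_rate_per_100[nrow(vte)] - vte$ppx_rate_per_100[1], 20
  )
  # monotone trend across deciles
  expect_gte(
    stats::cor(seq_len(nrow(vte)), vte$ppx_rate_per_100, method = "spearman"),
    0.9
  )
  bleed <- rep[rep$axis == "bleed" & rep$n > 0, ]
  expect_lt(max(abs(bleed$ppx_rate_per_100 - overall)), 10)
})

test_that("marginal fidelity holds across seeds", {
  meds_v <- meds_b <- numeric(20)
  for (i in 1:20) {
    co <- generate_cohort(synth_config(seed = 1000L + i))
    meds_v[i] <- median(co$p_vte)
    meds_b[i] <- median(co$p_bleed)
  }
  expect_lt(abs(mean(meds_v) / 0.0074 - 1), 0.05)
  expect_lt(abs(mean(meds_b) / 0.0021 - 1), 0.05)
})

test_that("clipping preserves risk ordering outside the clamped tails", {
  cfg <- synth_config(n = 5000L, seed = 77L)
  co <- generate_cohort(cfg)
  inner <- co$p_vte > cfg$vte_clip[1] & co$p_vte < cfg$vte_clip[2]
  # within the unclamped interior the ranks of p_vte and of its latent log
  # are identical by monotonicity of exp
  expect_equal(
    rank(co$p_vte[inner]),
    rank(log(co$p_vte[inner]))
  )
  expect_true(all(co$p_vte >= cfg$vte_clip[1] & co$p_vte <= cfg$vte_clip[2]))
})

test_that("score threshold crossings track the probability thresholds", {
  # noiseless scores: Padua >= 4 coincides with VTE risk >= 1% (up to
  # boundary ties), IMPROVE >= 7 with bleeding risk >= 0.78%
  co0 <- generate_cohort(synth_config(n = 8000L, seed = 3L, score_noise = 0))
  agree_v <- mean((co0$padua_score >= 4) == (co0$p_vte >= 0.01))
  agree_b <- mean((co0$improve_score >= 7) == (co0$p_bleed >= 0.0078))
  expect_gt(agree_v, 0.99)
  expect_gt(agree_b, 0.99)
  # default noise: crossings correlate without being identical
  co1 <- generate_cohort(synth_config(n = 8000L, seed = 3L, score_noise = 0.5))
  agree_v1 <- mean((co1$padua_score >= 4) == (co1$p_vte >= 0.01))
  expect_gt(agree_v1, 0.7)
  expect_lt(agree_v1, agree_v)
  # prevalence of high score matches prevalence of high predicted risk
  expect_equal(mean(co1$padua_score >= 4), mean(co1$p_vte >= 0.01),
    tolerance = 0.02
  )
})

test_that("infeasible calibration targets and bad configs are rejected", {
  expect_error(
    generate_cohort(synth_config(
      n = 500L,
      physician_low_rate = 0.7, physician_overall_rate = 0.6
    )),
    class = "vteprophy_calibration_error"
  )
  expect_error(synth_config(vte_mean = 0.005, vte_median = 0.007),
    class = "vteprophy_config_error"
  )
  expect_error(synth_config(log_risk_correlation = 1),
    class = "vteprophy_config_error"
  )
  expect_error(synth_config(bleed_clip = c(0.2, 0.1)),
    class = "vteprophy_config_error"
  )
})

test_that("quantile report handles the degenerate prescribing patterns", {
  set.seed(55)
  n <- 2000
  pv <- exp(rnorm(n, log(0.01), 0.8))
  pv <- pmin(pv, 0.9)
  # prescribing independent of risk
  co_null <- make_cohort(pv, rep(0.002, n), ppx = runif(n) < 0.6)
  rep_null <- quantile_prescribing_report(co_null, 4)
  vte_null <- rep_null[rep_null$axis == "vte", ]
  expect_true(all(abs(vte_null$ppx_rate_per_100 - 60) < 6))
  # treat exactly the top half of VTE risk
  co_sorted <- make_cohort(pv, rep(0.002, n), ppx = rank(pv) > n / 2)
  rep_sorted <- quantile_prescribing_report(co_sorted, 2)
  expect_equal(
    rep_sorted$ppx_rate_per_100[rep_sorted$axis == "vte"],
    c(0, 100)
  )
  expect_error(quantile_prescribing_report(co_null, n + 1),
    class = "vteprophy_config_error"
  )
})

test_that("generated cohorts carry provenance metadata", {
  cfg <- synth_config(n = 50L, seed = 12L)
  co <- generate_cohort(cfg)
  meta <- cohort_metadata(co)
  expect_equal(meta$seed, 12L)
  expect_equal(meta$config_digest, config_digest(cfg))
  expect_false(config_digest(cfg) == config_digest(synth_config(n = 51L, seed = 12L)))
})
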