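# Shared fixtures and independent straight-line oracles. The oracles
# deliberately avoid the package's vectorised code paths: plain loops over
# patients and pairwise/segment dominance checks.

make_cohort <- function(p_vte, p_bleed,
                        padua = rep(0L, length(p_vte)),
                        improve = rep(0L, length(p_vte)),
                        ppx = rep(FALSE, length(p_vte)),
                        ids = NULL) {
  n <- length(p_vte)
  new_cohort(data.frame(
    patient_id = ids %||% paste0("pt", seq_len(n)),
    p_vte = p_vte,
    p_bleed = p_bleed,
    padua_score = padua,
    improve_score = improve,
    physician_prophylaxis = ppx
  ))
}

random_cohort <- function(n, seed) {
  set.seed(seed)
  make_cohort(
    p_vte = exp(rnorm(n, log(0.008), 1)),
    p_bleed = exp(rnorm(n, log(0.002), 1.2)),
    padua = sample(0:10, n, replace = TRUE),
    improve = sample(0:12, n, replace = TRUE),
    ppx = runif(n) < 0.6
  )
}

# Straight-line reimplementation of the counterfactual expectation:
# explicit per-patient loop, no shared code with the package internals.
brute_expected_rates <- function(cohort, indications, efficacy_rrr, harm_rr) {
  n <- nrow(cohort)
  vte_sum <- 0
  bleed_sum <- 0
  for (i in seq_len(n)) {
    pv <- cohort$p_vte[i]
    pb <- cohort$p_bleed[i]
    if (indications[i]) {
      pv <- pv * (1 - efficacy_rrr)
      pb <- min(pb * harm_rr, 1)
    }
    vte_sum <- vte_sum + pv
    bleed_sum <- bleed_sum + pb
  }
  c(vte_per_1000 = 1000 * vte_sum / n, bleed_per_1000 = 1000 * bleed_sum / n)
}

# Straight-line strategy rules (per-patient loop).
brute_indication <- function(cohort, name, efficacy_rrr = 0.52, harm_rr = 1.37,
                             vte_thr = 0.01, bleed_thr = 0.0078,
                             padua_min = 4, improve_max = 7) {
  n <- nrow(cohort)
  out <- logical(n)
  for (i in seq_len(n)) {
    pv <- cohort$p_vte[i]
    pb <- cohort$p_bleed[i]
    out[i] <- switch(name,
      no_prophylaxis = FALSE,
      physicians = cohort$physician_prophylaxis[i],
      guidelines = cohort$padua_score[i] >= padua_min &&
        cohort$improve_score[i] < improve_max,
      cc_minimize_bleeding = pv >= vte_thr && pb < bleed_thr,
      cc_minimize_events = pv >= vte_thr &&
        (pb < bleed_thr || efficacy_rrr * pv > (harm_rr - 1) * pb),
      near_universal = pb < bleed_thr
    )
  }
  out
}

# Brute-force dominance: point i is dominated iff some other single point
# weakly beats it on both axes (strictly on at least one), or some convex
# combination of two other points reaches <= its treatment rate with
# strictly fewer events (extended dominance via the segment crossing x_i).
brute_dominated <- function(p, e, tol = 1e-9) {
  n <- length(p)
  dom <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j == i) next
      if (p[j] <= p[i] + tol && e[j] < e[i] - tol) dom[i] <- TRUE
      if (p[j] < p[i] - tol && e[j] <= e[i] + tol) dom[i] <- TRUE
    }
    for (j in seq_len(n)) {
      for (k in seq_len(n)) {
        if (j == i || k == i || p[j] >= p[k]) next
        if (p[j] < p[i] - tol && p[i] < p[k] + tol) {
          lambda <- (p[i] - p[j]) / (p[k] - p[j])
          e_mix <- (1 - lambda) * e[j] + lambda * e[k]
          if (e_mix < e[i] - tol) dom[i] <- TRUE
        }
      }
    }
  }
  dom
}

outcome_from_pe <- function(strategy, p, total_per_1000,
                            params = prophylaxis_params()) {
  strategy_outcome(strategy, p,
    vte_per_1000 = total_per_1000, bleed_per_1000 = 0,
    params = params
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
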