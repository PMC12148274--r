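#' Adjust per-patient risks for prophylaxis
#'
#' For treated patients the VTE probability is multiplied by
#' `1 - efficacy_rrr` and the bleeding probability by `harm_rr`, capped at 1
#' (a probability cannot exceed certainty; the cap can bind only for
#' extreme-bleeding-risk patients). Untreated patients keep their predicted
#' risks.
#'
#' @param p_vte,p_bleed Numeric vectors of probabilities in (0, 1).
#' @param treated Logical vector (recycled if length 1).
#' @param params A [prophylaxis_params()].
#' @return A tibble with adjusted columns `p_vte` and `p_bleed`.
#' @export
adjust_risks <- function(p_vte, p_bleed, treated, params = prophylaxis_params()) {
  if (!inherits(params, "prophylaxis_params")) {
    abort("params must be prophylaxis_params", class = "vteprophy_config_error")
  }
  n <- length(p_vte)
  if (length(treated) == 1) treated <- rep(treated, n)
  stopifnot(length(p_bleed) == n, length(treated) == n)
  tibble::tibble(
    p_vte = ifelse(treated, p_vte * (1 - params$efficacy_rrr), p_vte),
    p_bleed = ifelse(treated, pmin(p_bleed * params$harm_rr, 1), p_bleed)
  )
}

#' Build a strategy outcome row
#'
#' Container for a strategy's summary under one efficacy/harm assumption:
#' prophylaxis rate per 100 patients, and expected VTE, bleeding and total
#' events per 1,000 patients. Total is always VTE + bleeding.
#'
#' @param strategy Strategy label.
#' @param prophylaxis_per_100 Treatment rate per 100 patients.
#' @param vte_per_1000,bleed_per_1000 Expected events per 1,000 patients.
#' @param params The [prophylaxis_params()] under which the rates were
#'   computed.
#' @return A one-row tibble of class `strategy_outcome` with columns
#'   `strategy`, `efficacy_rrr`, `harm_rr`, `prophylaxis_per_100`,
#'   `vte_per_1000`, `bleed_per_1000`, `total_per_1000`.
#' @export
strategy_outcome <- function(strategy, prophylaxis_per_100,
                             vte_per_1000, bleed_per_1000,
                             params = prophylaxis_params()) {
  stopifnot(
    prophylaxis_per_100 >= 0, prophylaxis_per_100 <= 100,
    vte_per_1000 >= 0, bleed_per_1000 >= 0
  )
  structure(
    tibble::tibble(
      strategy = strategy,
      efficacy_rrr = params$efficacy_rrr,
      harm_rr = params$harm_rr,
      prophylaxis_per_100 = prophylaxis_per_100,
      vte_per_1000 = vte_per_1000,
      bleed_per_1000 = bleed_per_1000,
      total_per_1000 = vte_per_1000 + bleed_per_1000
    ),
    class = c("strategy_outcome", class(tibble::tibble()))
  )
}

#' Expected events under an indication vector
#'
#' The analytic counterfactual estimate: each patient's risks are adjusted
#' for their indication, summed over the cohort, divided by the cohort size
#' and scaled to events per 1,000 patients. VTE and major bleeding are
#' treated as independent, non-competing risks, so the totals add.
#'
#' @param cohort A `vte_cohort`.
#' @param indications Logical vector of the same length as the cohort.
#' @param params A [prophylaxis_params()].
#' @param name Strategy label stored in the outcome.
#' @return A [strategy_outcome()] row.
#' @export
expected_events <- function(cohort, indications, params = prophylaxis_params(),
                            name = "strategy") {
  assert_cohort(cohort)
  if (length(indications) != nrow(cohort)) {
    abort(
      paste0(
        "indications length (", length(indications),
        ") does not match cohort size (", nrow(cohort), ")"
      ),
      class = "vteprophy_config_error"
    )
  }
  adj <- adjust_risks(cohort$p_vte, cohort$p_bleed, indications, params)
  strategy_outcome(
    strategy = name,
    prophylaxis_per_100 = prophylaxis_rate(indications),
    vte_per_1000 = 1000 * mean(adj$p_vte),
    bleed_per_1000 = 1000 * mean(adj$p_bleed),
    params = params
  )
}

#' Evaluate several strategies on one cohort
#'
#' Convenience wrapper: assigns indications and computes expected events for
#' each requested strategy under a single set of treatment-effect parameters.
#'
#' @param cohort A `vte_cohort`.
#' @param strategies A character vector of strategy names and/or a list of
#'   [strategy_spec()] objects. Defaults to all six strategies (the
#'   `no_prophylaxis` reference first).
#' @param params A [prophylaxis_params()].
#' @return A tibble of [strategy_outcome()] rows, one per strategy.
#' @export
evaluate_strategies <- function(cohort, strategies = STRATEGY_NAMES,
                                params = prophylaxis_params()) {
  assert_cohort(cohort)
  specs <- as_strategy_specs(strategies)
  dplyr::bind_rows(lapply(specs, function(spec) {
    ind <- assign_prophylaxis(cohort, spec, params)
    expected_events(cohort, ind, params, name = spec$name)
  }))
}

#' Monte-Carlo simulation of event counts
#'
#' Independent oracle for [expected_events()]: in each replicate every
#' patient's VTE and bleeding events are drawn as independent Bernoulli
#' trials at the adjusted probabilities, and the counts are totalled.
#' Reproducible under a fixed seed without disturbing the caller's RNG
#' state.
#'
#' @param cohort A `vte_cohort`.
#' @param indications Logical vector of per-patient indications.
#' @param params A [prophylaxis_params()].
#' @param n_reps Number of replicates (>= 1).
#' @param seed Integer seed.
#' @return A list of class `vte_simulation` with integer vectors
#'   `vte_counts` and `bleed_counts` (length `n_reps`), the cohort size `n`,
#'   and `mean_vte_per_1000`, `se_vte_per_1000`, `mean_bleed_per_1000`,
#'   `se_bleed_per_1000` (Monte-Carlo mean and standard error of the
#'   per-1,000 rates).
#' @export
simulate_events <- function(cohort, indications, params = prophylaxis_params(),
                            n_reps = 1000L, seed = 1L) {
  assert_cohort(cohort)
  if (length(indications) != nrow(cohort)) {
    abort("indications length does not match cohort size",
      class = "vteprophy_config_error"
    )
  }
  if (n_reps < 1) abort("n_reps must be >= 1", class = "vteprophy_config_error")
  adj <- adjust_risks(cohort$p_vte, cohort$p_bleed, indications, params)
  n <- nrow(cohort)
  pv <- adj$p_vte
  pb <- adj$p_bleed
  vte_counts <- integer(n_reps)
  bleed_counts <- integer(n_reps)
  # chunk replicates so each uniform draw block stays ~2e7 doubles
  chunk <- max(1L, min(n_reps, as.integer(ceiling(2e7 / n))))
  with_seed(seed, {
    at <- 1L
    while (at <= n_reps) {
      k <- min(chunk, n_reps - at + 1L)
      idx <- at:(at + k - 1L)
      vte_counts[idx] <- as.integer(.colSums(runif(n * k) < pv, n, k))
      bleed_counts[idx] <- as.integer(.colSums(runif(n * k) < pb, n, k))
      at <- at + k
    }
  })
  se <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  structure(
    list(
      vte_counts = vte_counts,
      bleed_counts = bleed_counts,
      n = n,
      n_reps = n_reps,
      mean_vte_per_1000 = 1000 * mean(vte_counts) / n,
      se_vte_per_1000 = 1000 * se(vte_counts) / n,
      mean_bleed_per_1000 = 1000 * mean(bleed_counts) / n,
      se_bleed_per_1000 = 1000 * se(bleed_counts) / n
    ),
    class = "vte_simulation"
  )
}

#' @export
print.vte_simulation <- function(x, ...) {
  cat(
    "<vte_simulation> ", x$n_reps, " replicates over ", x$n, " patients\n",
    "  VTE per 1,000:   ", format(x$mean_vte_per_1000, digits = 4),
    " (SE ", format(x$se_vte_per_1000, digits = 3), ")\n",
    "  bleed per 1,000: ", format(x$mean_bleed_per_1000, digits = 4),
    " (SE ", format(x$se_bleed_per_1000, digits = 3), ")\n",
    sep = ""
  )
  invisible(x)
}
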