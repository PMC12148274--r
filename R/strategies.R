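#' Prophylaxis treatment-effect parameters
#'
#' The counterfactual adjustment applied to a treated patient's risks:
#' `efficacy_rrr` is the relative risk reduction in VTE probability
#' (base case 0.52, plausible range 0.27-0.52 from the prophylaxis RCTs) and
#' `harm_rr` is the relative risk multiplier on major-bleeding probability
#' (base case 1.37, plausible range 1.37-1.92).
#'
#' @param efficacy_rrr Relative VTE reduction, a fraction in (0, 1).
#' @param harm_rr Bleeding multiplier, >= 1.
#' @return A list of class `prophylaxis_params`.
#' @export
prophylaxis_params <- function(efficacy_rrr = 0.52, harm_rr = 1.37) {
  if (!is.numeric(efficacy_rrr) || length(efficacy_rrr) != 1 ||
    is.na(efficacy_rrr) || efficacy_rrr <= 0 || efficacy_rrr >= 1) {
    abort("efficacy_rrr must be a single number strictly between 0 and 1",
      class = "vteprophy_config_error"
    )
  }
  if (!is.numeric(harm_rr) || length(harm_rr) != 1 || is.na(harm_rr) || harm_rr < 1) {
    abort("harm_rr must be a single number >= 1", class = "vteprophy_config_error")
  }
  structure(
    list(efficacy_rrr = efficacy_rrr, harm_rr = harm_rr),
    class = "prophylaxis_params"
  )
}

#' Specify a prophylaxis strategy
#'
#' Six decision rules are supported, each mapping patient features to a
#' prophylaxis indication:
#'
#' * `no_prophylaxis` — treat nobody (the reference point of the frontier).
#' * `physicians` — the observed prescribing flag.
#' * `guidelines` — Padua score >= `padua_min` and IMPROVE score
#'   < `improve_max` (the ASH score-based rule).
#' * `cc_minimize_bleeding` — predicted VTE risk >= `vte_threshold` and
#'   predicted bleeding risk < `bleed_threshold`.
#' * `cc_minimize_events` — as `cc_minimize_bleeding`, but a high-bleeding
#'   patient is also treated when their VTE risk outweighs their bleeding
#'   risk (see `weighing_mode`).
#' * `near_universal` — predicted bleeding risk < `bleed_threshold`,
#'   regardless of VTE risk.
#'
#' Boundary directions are fixed: the VTE and Padua thresholds are inclusive,
#' the bleeding and IMPROVE thresholds exclusive.
#'
#' `weighing_mode` controls the risk comparison in `cc_minimize_events`:
#' `"expected_events"` (default) treats when the expected VTEs prevented
#' exceed the expected bleeds caused, `efficacy_rrr * p_vte >
#' (harm_rr - 1) * p_bleed`; `"raw_risk"` treats when `p_vte > p_bleed`.
#' Ties are not treated (strict inequality in both modes).
#'
#' @param name One of the six strategy names above.
#' @param padua_min Inclusive Padua high-VTE-risk threshold (points).
#' @param improve_max Exclusive IMPROVE low-bleeding-risk bound (points).
#' @param vte_threshold Inclusive high-VTE-risk probability threshold.
#' @param bleed_threshold Exclusive low-bleeding-risk probability bound.
#' @param weighing_mode `"expected_events"` or `"raw_risk"`.
#' @return A list of class `strategy_spec`.
#' @export
strategy_spec <- function(name,
                          padua_min = 4L,
                          improve_max = 7L,
                          vte_threshold = 0.01,
                          bleed_threshold = 0.0078,
                          weighing_mode = c("expected_events", "raw_risk")) {
  if (length(name) != 1 || !name %in% STRATEGY_NAMES) {
    abort(
      paste0(
        "unknown strategy name ", deparse(name), "; expected one of: ",
        paste(STRATEGY_NAMES, collapse = ", ")
      ),
      class = "vteprophy_config_error"
    )
  }
  weighing_mode <- match.arg(weighing_mode)
  if (vte_threshold <= 0 || bleed_threshold <= 0) {
    abort("risk thresholds must be strictly positive",
      class = "vteprophy_config_error"
    )
  }
  structure(
    list(
      name = name,
      padua_min = as.integer(padua_min),
      improve_max = as.integer(improve_max),
      vte_threshold = vte_threshold,
      bleed_threshold = bleed_threshold,
      weighing_mode = weighing_mode
    ),
    class = "strategy_spec"
  )
}

# Coerce strategy names and/or specs to a named list of strategy_spec.
as_strategy_specs <- function(strategies, ...) {
  if (inherits(strategies, "strategy_spec")) strategies <- list(strategies)
  specs <- lapply(strategies, function(s) {
    if (inherits(s, "strategy_spec")) s else strategy_spec(s, ...)
  })
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Assign prophylaxis indications under a strategy
#'
#' Applies the deterministic decision rule of `spec` to every patient.
#' `params` enters only through the `cc_minimize_events` weighing rule in
#' `"expected_events"` mode.
#'
#' @param cohort A `vte_cohort`.
#' @param spec A [strategy_spec()] (or a strategy name, coerced with default
#'   thresholds).
#' @param params A [prophylaxis_params()].
#' @return A logical vector, one indication per patient, in cohort order.
#' @export
assign_prophylaxis <- function(cohort, spec, params = prophylaxis_params()) {
  assert_cohort(cohort)
  if (is.character(spec)) spec <- strategy_spec(spec)
  if (!inherits(spec, "strategy_spec")) {
    abort("spec must be a strategy_spec", class = "vteprophy_config_error")
  }
  if (!inherits(params, "prophylaxis_params")) {
    abort("params must be prophylaxis_params", class = "vteprophy_config_error")
  }
  pv <- cohort$p_vte
  pb <- cohort$p_bleed
  switch(spec$name,
    no_prophylaxis = rep(FALSE, nrow(cohort)),
    physicians = cohort$physician_prophylaxis,
    guidelines = {
      if (anyNA(cohort$padua_score) || anyNA(cohort$improve_score)) {
        abort(
          "the guidelines strategy needs Padua and IMPROVE scores for every patient",
          class = "vteprophy_config_error"
        )
      }
      cohort$padua_score >= spec$padua_min & cohort$improve_score < spec$improve_max
    },
    cc_minimize_bleeding = pv >= spec$vte_threshold & pb < spec$bleed_threshold,
    cc_minimize_events = {
      favorable <- switch(spec$weighing_mode,
        expected_events = params$efficacy_rrr * pv > (params$harm_rr - 1) * pb,
        raw_risk = pv > pb
      )
      pv >= spec$vte_threshold & (pb < spec$bleed_threshold | favorable)
    },
    near_universal = pb < spec$bleed_threshold
  )
}

#' Prophylaxis rate per 100 patients
#'
#' @param indications A non-empty logical vector of per-patient indications.
#' @return `100 * mean(indications)`.
#' @export
prophylaxis_rate <- function(indications) {
  if (length(indications) == 0) {
    abort("indications vector is empty", class = "vteprophy_config_error")
  }
  if (anyNA(indications)) {
    abort("indications must not contain NA", class = "vteprophy_validation_error")
  }
  100 * mean(indications)
}
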