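#' Sweep strategies over an efficacy-by-harm grid
#'
#' Re-runs the full evaluation (indication assignment, expected events,
#' frontier) for every combination of efficacy and harm values. By default
#' the grid is the four corners of the published plausible ranges:
#' efficacy 27% or 52% VTE reduction, harm 37% or 92% bleeding increase.
#'
#' Within each cell the indications are re-derived under the cell's
#' parameters, so `cc_minimize_events` membership responds to the assumed
#' efficacy and harm; set `refresh_indications = FALSE` to freeze membership
#' at `base_params` and vary only the risk adjustment.
#'
#' @param cohort A `vte_cohort`.
#' @param strategies Strategy names and/or [strategy_spec()] objects
#'   (default: all six).
#' @param efficacy_values Relative VTE reductions to sweep.
#' @param harm_values Bleeding risk multipliers to sweep.
#' @param refresh_indications Re-derive indications per cell (default) or
#'   freeze them at `base_params`.
#' @param base_params Parameters used for indication assignment when
#'   `refresh_indications = FALSE`.
#' @return A list of class `vte_sensitivity`; each element is a cell with
#'   `efficacy_rrr`, `harm_rr`, `outcomes` (tibble of strategy outcomes) and
#'   `frontier` ([build_frontier()] result, `NULL` when fewer than two
#'   strategies were requested).
#' @export
run_grid <- function(cohort, strategies = STRATEGY_NAMES,
                     efficacy_values = c(0.27, 0.52),
                     harm_values = c(1.37, 1.92),
                     refresh_indications = TRUE,
                     base_params = prophylaxis_params()) {
  assert_cohort(cohort)
  if (length(efficacy_values) == 0 || length(harm_values) == 0) {
    abort("the sensitivity grid must contain at least one efficacy and one harm value",
      class = "vteprophy_config_error"
    )
  }
  specs <- as_strategy_specs(strategies)
  cells <- list()
  for (eff in efficacy_values) {
    for (harm in harm_values) {
      params <- prophylaxis_params(efficacy_rrr = eff, harm_rr = harm)
      assign_params <- if (refresh_indications) params else base_params
      outcomes <- dplyr::bind_rows(lapply(specs, function(spec) {
        ind <- assign_prophylaxis(cohort, spec, assign_params)
        expected_events(cohort, ind, params, name = spec$name)
      }))
      frontier <- if (nrow(outcomes) >= 2) build_frontier(outcomes) else NULL
      cells[[length(cells) + 1]] <- list(
        efficacy_rrr = eff,
        harm_rr = harm,
        outcomes = outcomes,
        frontier = frontier
      )
    }
  }
  structure(cells,
    class = "vte_sensitivity",
    weighing_mode = vapply(specs, `[[`, character(1), "weighing_mode")[1],
    refresh_indications = refresh_indications
  )
}

# Display order of strategies in rendered sensitivity blocks.
REPORT_ORDER <- c(
  "physicians", "guidelines", "cc_minimize_bleeding",
  "cc_minimize_events", "near_universal"
)

#' Render a sensitivity grid as a plain-text table
#'
#' One block per grid cell, with strategies in the conventional order
#' (physicians, guidelines, CC minimize-bleeding, CC minimize-events,
#' near-universal), event rates per 1,000 to two decimals, and incremental
#' NNTs shown only for strategies with dominant efficiency (`-` otherwise;
#' the `no_prophylaxis` reference anchors the frontier but is not listed).
#'
#' @param cells A [run_grid()] result.
#' @return A character scalar (the formatted report).
#' @export
render_table <- function(cells) {
  if (length(cells) < 1) {
    abort("no sensitivity cells to render", class = "vteprophy_config_error")
  }
  lines <- character(0)
  header <- sprintf(
    "%-22s %12s %14s %12s %12s %12s",
    "Strategy", "Ppx per 100", "VTE per 1,000", "Bleed /1,000", "Total /1,000",
    "Incr. NNT"
  )
  for (cell in cells) {
    lines <- c(lines, sprintf(
      "Efficacy %.0f%% (VTE reduction), Harm %.0f%% (bleeding increase)",
      100 * cell$efficacy_rrr, 100 * (cell$harm_rr - 1)
    ), header)
    tab <- if (is.null(cell$frontier)) {
      out <- cell$outcomes
      out$dominated <- NA
      out$anchor <- NA
      out$incremental_nnt <- NA_real_
      out
    } else {
      cell$frontier
    }
    present <- intersect(REPORT_ORDER, tab$strategy)
    for (s in present) {
      row <- tab[tab$strategy == s, ][1, ]
      show_nnt <- isTRUE(!row$dominated) && isTRUE(!row$anchor) &&
        is.finite(row$incremental_nnt)
      nnt_txt <- if (show_nnt) {
        formatC(round_nnt(row$incremental_nnt),
          format = "d", big.mark = ","
        )
      } else {
        "-"
      }
      lines <- c(lines, sprintf(
        "%-22s %12.1f %14.2f %12.2f %12.2f %12s",
        s, row$prophylaxis_per_100, row$vte_per_1000, row$bleed_per_1000,
        row$total_per_1000, nnt_txt
      ))
    }
    lines <- c(lines, "")
  }
  paste(lines, collapse = "\n")
}

#' Long-format sensitivity results
#'
#' Machine-readable companion to [render_table()]: one row per cell and
#' strategy with the full-precision rates, dominance flags and NNTs.
#'
#' @param cells A [run_grid()] result.
#' @return A tibble with columns `efficacy_rrr`, `harm_rr`, `strategy`,
#'   `prophylaxis_per_100`, `vte_per_1000`, `bleed_per_1000`,
#'   `total_per_1000`, `dominated`, `anchor`, `incremental_nnt`.
#' @export
sensitivity_long <- function(cells) {
  dplyr::bind_rows(lapply(cells, function(cell) {
    tab <- if (is.null(cell$frontier)) cell$outcomes else cell$frontier
    tibble::as_tibble(tab)
  }))
}

#' @export
print.vte_sensitivity <- function(x, ...) {
  cat(render_table(x))
  invisible(x)
}
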