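#' Incremental number needed to treat between two strategies
#'
#' The additional patients treated per additional event prevented when moving
#' from the less-treating `base` strategy to the more-treating `comparator`:
#' `(P2 - P1) / (E1 - E2)`, with P the prophylaxis rate per 100 patients and
#' E the expected total events per 100 patients (both cohort-wide).
#'
#' If the comparator prevents no additional events (`E1 <= E2`) the NNT is
#' non-finite (`Inf`), which marks the comparator as dominated in frontier
#' construction.
#'
#' @param base,comparator [strategy_outcome()] rows (or any one-row data
#'   frames with `prophylaxis_per_100` and `total_per_1000`);
#'   `comparator` must treat more patients than `base`.
#' @return The incremental NNT (possibly `Inf`).
#' @export
incremental_nnt <- function(base, comparator) {
  p1 <- base$prophylaxis_per_100
  p2 <- comparator$prophylaxis_per_100
  e1 <- base$total_per_1000 / 10
  e2 <- comparator$total_per_1000 / 10
  if (p2 <= p1) {
    abort(
      "comparator must have a higher prophylaxis rate than base; swap the arguments or reject the pair",
      class = "vteprophy_config_error"
    )
  }
  if (e1 <= e2) {
    return(Inf)
  }
  (p2 - p1) / (e1 - e2)
}

#' Round an NNT for display
#'
#' NNTs above 100 are rounded to the nearest 5, smaller ones to the nearest
#' integer; full precision is kept in machine-readable output.
#'
#' @param nnt Numeric vector of NNTs.
#' @return Rounded NNTs (`NA` where non-finite).
#' @export
round_nnt <- function(nnt) {
  out <- ifelse(is.finite(nnt), ifelse(nnt > 100, round(nnt / 5) * 5, round(nnt)), NA_real_)
  out
}

# Indices of the strict lower-convex-hull vertices of (x, y), x sorted
# ascending with unique x. Collinear interior points are dropped.
lower_hull_idx <- function(x, y) {
  n <- length(x)
  if (n <= 2) {
    return(seq_len(n))
  }
  hull <- integer(0)
  for (i in seq_len(n)) {
    while (length(hull) >= 2) {
      o <- hull[length(hull) - 1]
      a <- hull[length(hull)]
      cross <- (x[a] - x[o]) * (y[i] - y[o]) - (y[a] - y[o]) * (x[i] - x[o])
      if (cross <= 0) hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  hull
}

#' Build the prophylaxis efficiency frontier
#'
#' Orders strategy outcomes by prophylaxis rate, identifies dominated
#' strategies, and computes incremental NNTs along the frontier. The
#' frontier is the lower convex hull of (prophylaxis rate per 100, total
#' events per 100), walked from the least-treating point (the anchor,
#' normally `no_prophylaxis`) while total events strictly decrease. A
#' strategy strictly above the hull is dominated — either directly (another
#' strategy treats no more patients and causes fewer events) or by extended
#' dominance (a blend of two strategies beats it), the standard frontier
#' rule in cost-effectiveness analysis. Strategies with identical
#' coordinates are collapsed onto one frontier point.
#'
#' @param outcomes A tibble of at least two [strategy_outcome()] rows, all
#'   computed under identical efficacy/harm parameters.
#' @return A tibble of class `vte_frontier`: the outcome columns plus
#'   `anchor`, `dominated` and `incremental_nnt` (NNT from the previous
#'   frontier point; `NA` for the anchor and for dominated strategies),
#'   ordered by ascending prophylaxis rate.
#' @export
build_frontier <- function(outcomes) {
  outcomes <- tibble::as_tibble(outcomes)
  if (nrow(outcomes) < 2) {
    abort("need at least two strategy outcomes to build a frontier",
      class = "vteprophy_config_error"
    )
  }
  if (dplyr::n_distinct(outcomes$efficacy_rrr) != 1 ||
    dplyr::n_distinct(outcomes$harm_rr) != 1) {
    abort("all outcomes on one frontier must share the same efficacy/harm parameters",
      class = "vteprophy_config_error"
    )
  }
  ord <- order(outcomes$prophylaxis_per_100, outcomes$total_per_1000)
  res <- outcomes[ord, ]
  p <- res$prophylaxis_per_100
  e <- res$total_per_1000 / 10

  # hull candidates: for tied prophylaxis rates only the lowest event rate
  first_at_p <- !duplicated(p)
  cand <- which(first_at_p)
  hull_local <- lower_hull_idx(p[cand], e[cand])
  hull <- cand[hull_local]
  # frontier: walk the hull left to right while events strictly decrease
  keep <- 1L
  for (i in seq_along(hull)[-1]) {
    if (e[hull[i]] < e[hull[keep[length(keep)]]]) keep <- c(keep, i) else break
  }
  front <- hull[keep]

  tol <- 1e-9 * max(1, max(abs(p)), max(abs(e)))
  coord_match <- function(i, j) abs(p[i] - p[j]) <= tol & abs(e[i] - e[j]) <= tol
  on_front <- rep(FALSE, nrow(res))
  front_of <- rep(NA_integer_, nrow(res)) # which frontier vertex a row collapses onto
  for (k in seq_along(front)) {
    m <- which(coord_match(seq_len(nrow(res)), front[k]))
    on_front[m] <- TRUE
    front_of[m] <- k
  }

  nnt_by_vertex <- rep(NA_real_, length(front))
  for (k in seq_along(front)[-1]) {
    nnt_by_vertex[k] <- incremental_nnt(res[front[k - 1], ], res[front[k], ])
  }
  res$anchor <- !is.na(front_of) & front_of == 1L
  res$dominated <- !on_front
  res$incremental_nnt <- ifelse(is.na(front_of), NA_real_, nnt_by_vertex[front_of])
  structure(res, class = c("vte_frontier", class(tibble::tibble())))
}

#' Plot an efficiency frontier
#'
#' Prophylaxis rate versus total expected events per 1,000 patients, with
#' the frontier drawn through non-dominated strategies and incremental NNTs
#' labelled. Requires ggplot2.
#'
#' @param frontier A [build_frontier()] result.
#' @return A ggplot object.
#' @export
plot_frontier <- function(frontier) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("plot_frontier() needs the ggplot2 package",
      class = "vteprophy_config_error"
    )
  }
  front <- frontier[!frontier$dominated, ]
  lab <- front[!front$anchor, ]
  lab$label <- paste0("NNT ", format(round_nnt(lab$incremental_nnt), big.mark = ","))
  ggplot2::ggplot(
    frontier,
    ggplot2::aes(x = .data$prophylaxis_per_100, y = .data$total_per_1000)
  ) +
    ggplot2::geom_line(data = front, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$dominated), size = 2.5) +
    ggplot2::geom_text(
      data = frontier,
      ggplot2::aes(label = .data$strategy),
      vjust = -1, size = 3
    ) +
    ggplot2::geom_label(
      data = lab, ggplot2::aes(label = .data$label),
      vjust = 2, size = 3
    ) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::labs(
      x = "Prophylaxis rate (per 100 patients)",
      y = "Total expected events (per 1,000 patients)",
      shape = "Dominated"
    ) +
    ggplot2::theme_minimal()
}
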