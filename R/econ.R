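#' Strategy outcome: discounted totals for one strategy
#'
#' A thin constructor for the (label, cost, effect) triple that the
#' incremental analysis consumes; [evaluate_strategy()] produces a
#' compatible (richer) row.
#'
#' @param label Strategy name.
#' @param cost Discounted total cost (>= 0).
#' @param effect Discounted total QALYs (>= 0).
#' @return A one-row tibble.
#' @examples
#' strategy_outcome("TCH", cost = 46395, effect = 3.65)
#' @export
strategy_outcome <- function(label, cost, effect) {
  if (cost < 0 || effect < 0) abort("`cost` and `effect` must be non-negative.")
  tibble(label = label, cost = cost, effect = effect)
}

#' Incremental cost-effectiveness comparison of two strategies
#'
#' Computes the incremental cost and effect of strategy `a` versus `b`,
#' the ICER (when the effect difference is non-zero), and the dominance
#' class: a strategy dominates when it is both cheaper and more effective,
#' in which case the ICER is negative and uninformative and the net
#' monetary benefit (see [nmb()]) is the recommended decision output.
#'
#' @param a,b One-row tibbles with `label`, `cost`, `effect` (from
#'   [evaluate_strategy()] or [strategy_outcome()]).
#' @return An object of class `cea_comparison` with elements
#'   `strategies`, `delta_cost`, `delta_effect`, `icer`, `icer_defined`,
#'   `dominance` (one of `"none"`, `"a_dominates"`, `"b_dominates"`).
#' @examples
#' incremental(strategy_outcome("ACTH", 59537, 3.4),
#'             strategy_outcome("TCH", 46395, 3.65))
#' @export
incremental <- function(a, b) {
  stopifnot(is.data.frame(a), is.data.frame(b),
            nrow(a) == 1L, nrow(b) == 1L)
  delta_cost <- a$cost - b$cost
  delta_effect <- a$effect - b$effect
  icer_defined <- delta_effect != 0
  icer <- if (icer_defined) delta_cost / delta_effect else NA_real_
  dominance <- if (delta_cost < 0 && delta_effect > 0) {
    "a_dominates"
  } else if (delta_cost > 0 && delta_effect < 0) {
    "b_dominates"
  } else {
    "none"
  }
  structure(
    list(
      strategies = dplyr::bind_rows(
        dplyr::select(a, "label", "cost", "effect"),
        dplyr::select(b, "label", "cost", "effect")
      ),
      label_a = a$label, label_b = b$label,
      delta_cost = delta_cost, delta_effect = delta_effect,
      icer = icer, icer_defined = icer_defined, dominance = dominance
    ),
    class = "cea_comparison"
  )
}

#' @export
print.cea_comparison <- function(x, ...) {
  cat(sprintf("<cea_comparison> %s vs %s\n", x$label_a, x$label_b))
  cat(sprintf("  delta cost:   %12.2f\n  delta effect: %12.4f QALYs\n",
              x$delta_cost, x$delta_effect))
  if (x$icer_defined) {
    cat(sprintf("  ICER:         %12.2f per QALY\n", x$icer))
  } else {
    cat("  ICER:         undefined (equal effects)\n")
  }
  if (x$dominance != "none") {
    dom <- if (x$dominance == "a_dominates") x$label_a else x$label_b
    cat(sprintf("  dominance:    %s dominates (cheaper and more effective)\n", dom))
  }
  invisible(x)
}

#' Net monetary benefit
#'
#' `NMB = wtp * effect - cost` at willingness-to-pay `wtp` per QALY.  The
#' strategy with the higher NMB at a given threshold is preferred; unlike
#' the ICER, the NMB stays interpretable when one strategy dominates.
#'
#' @param outcome Tibble of strategy outcomes (`label`, `cost`, `effect`),
#'   one or more rows.
#' @param wtp Willingness-to-pay threshold(s) per QALY; vectorised.
#'   Default 34,240 (China's 2015 GDP per capita in US dollars).
#' @return A tibble with `label`, `wtp`, `nmb` (one row per strategy x
#'   threshold).
#' @examples
#' nmb(strategy_outcome("TCH", 46395, 3.65), wtp = 34240) # 78,581
#' @export
nmb <- function(outcome, wtp = 34240) {
  stopifnot(is.data.frame(outcome), all(wtp >= 0))
  tidyr::crossing(dplyr::select(outcome, "label", "cost", "effect"),
                  wtp = wtp) |>
    dplyr::mutate(nmb = .data$wtp * .data$effect - .data$cost) |>
    dplyr::select("label", "wtp", "nmb")
}

#' Strategy results table
#'
#' Side-by-side per-strategy totals plus the incremental row, mirroring a
#' standard cost-effectiveness results table (intervention cost, health
#' system cost, total cost, QALYs, deltas, ICER).
#'
#' @param outcomes Tibble of [evaluate_strategy()] rows (two strategies).
#' @param comparison Optional `cea_comparison`; computed from the first
#'   two rows of `outcomes` when omitted.
#' @return A tibble in long item-by-strategy layout with a `deviation`
#'   column for the incremental quantities.
#' @export
results_table <- function(outcomes, comparison = NULL) {
  stopifnot(nrow(outcomes) >= 2L)
  if (is.null(comparison)) {
    comparison <- incremental(outcomes[1L, ], outcomes[2L, ])
  }
  a <- outcomes[1L, ]
  b <- outcomes[2L, ]
  get0num <- function(row, col) if (col %in% names(row)) row[[col]] else NA_real_
  tibble(
    item = c("intervention_cost", "health_system_cost", "cost", "qaly", "icer"),
    !!a$label := c(get0num(a, "intervention_cost"), get0num(a, "state_cost"),
                   a$cost, a$effect, NA_real_),
    !!b$label := c(get0num(b, "intervention_cost"), get0num(b, "state_cost"),
                   b$cost, b$effect, NA_real_),
    deviation = c(NA_real_, NA_real_, comparison$delta_cost,
                  comparison$delta_effect, comparison$icer)
  )
}
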