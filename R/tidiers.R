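#' Tidy an incremental comparison
#'
#' @param x A `cea_comparison`.
#' @param ... Unused.
#' @return One-row tibble: labels, deltas, `icer`, `dominance`.
#' @export
tidy.cea_comparison <- function(x, ...) {
  tibble(
    label_a = x$label_a, label_b = x$label_b,
    delta_cost = x$delta_cost, delta_effect = x$delta_effect,
    icer = x$icer, icer_defined = x$icer_defined, dominance = x$dominance
  )
}

#' @rdname tidy.cea_comparison
#' @export
glance.cea_comparison <- function(x, ...) tidy.cea_comparison(x, ...)

#' Tidy a cohort trace into long format
#'
#' @param x A `cohort_trace`.
#' @param ... Unused.
#' @return Tibble with `cycle`, `state`, `occupancy`.
#' @export
tidy.cohort_trace <- function(x, ...) {
  spec <- attr(x, "spec")
  tidyr::pivot_longer(as_tibble(x), cols = dplyr::all_of(spec$states),
                      names_to = "state", values_to = "occupancy") |>
    dplyr::mutate(state = factor(.data$state, levels = spec$states))
}

#' One-line summary of a cohort trace
#'
#' @param x A `cohort_trace`.
#' @param ... Unused.
#' @return One-row tibble: label, cycles, final death occupancy.
#' @export
glance.cohort_trace <- function(x, ...) {
  spec <- attr(x, "spec")
  tibble(label = spec$label, n_cycles = spec$n_cycles,
         discount_rate = spec$discount_rate,
         final_death = x$death[nrow(x)])
}

#' Tidy PSA draws
#'
#' @param x A `psa_result`.
#' @param ... Unused.
#' @return The draws as a plain tibble.
#' @export
tidy.psa_result <- function(x, ...) as_tibble(x)

#' Summarise a PSA: means and 95% percentile interval of the deltas
#'
#' @param x A `psa_result`.
#' @param ... Unused.
#' @return One-row tibble: `n_sims`, mean and 2.5/97.5-percentile bounds
#'   of `delta_cost` and `delta_effect`, and the rebalancing count.
#' @export
glance.psa_result <- function(x, ...) {
  ci <- psa_interval(x)
  tibble(
    n_sims = nrow(x),
    delta_cost_mean = ci$mean[ci$quantity == "delta_cost"],
    delta_cost_lo = ci$lo[ci$quantity == "delta_cost"],
    delta_cost_hi = ci$hi[ci$quantity == "delta_cost"],
    delta_effect_mean = ci$mean[ci$quantity == "delta_effect"],
    delta_effect_lo = ci$lo[ci$quantity == "delta_effect"],
    delta_effect_hi = ci$hi[ci$quantity == "delta_effect"],
    n_rebalanced = attr(x, "n_rebalanced") %||% 0L
  )
}
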