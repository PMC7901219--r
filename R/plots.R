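#' Plot a cohort trace
#'
#' State occupancy over cycles, one line per health state.
#'
#' @param object A `cohort_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cohort_trace <- function(object, ...) {
  spec <- attr(object, "spec")
  tidy.cohort_trace(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$cycle, y = .data$occupancy,
                                 colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(title = paste0("Cohort trace: ", spec$label),
                  x = "Cycle (years)", y = "State occupancy",
                  colour = "State") +
    ggplot2::theme_minimal()
}

#' Plot a tornado diagram
#'
#' Horizontal bars spanning each parameter's one-way output range,
#' widest swing on top, with the base-case output as a dashed line.
#'
#' @param object A `tornado_result`.
#' @param top Show only the `top` widest parameters (default all).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tornado_result <- function(object, top = NULL, ...) {
  d <- as_tibble(object)
  if (!is.null(top)) d <- utils::head(d, top)
  d$name <- factor(d$name, levels = rev(d$name))
  d$ymin <- pmin(d$out_lo, d$out_hi)
  d$ymax <- pmax(d$out_lo, d$out_hi)
  ggplot2::ggplot(d, ggplot2::aes(y = .data$name)) +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$ymin, xmax = .data$ymax),
                            linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = d$out_base[1], linetype = "dashed") +
    ggplot2::labs(title = "One-way sensitivity (tornado)",
                  x = paste0("Output (", attr(object, "output"), ")"),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the cost-effectiveness plane of a PSA
#'
#' Incremental (effect, cost) scatter for the second strategy versus the
#' first, with the willingness-to-pay ray; points on or below the ray are
#' cost-effective.
#'
#' @param object A `psa_result`.
#' @param wtp Willingness-to-pay ray (default 20,000).
#' @param ... Passed to [ce_plane()].
#' @return A ggplot.
#' @export
autoplot.psa_result <- function(object, wtp = 20000, ...) {
  plane <- ce_plane(object, wtp = wtp, ...)
  ggplot2::ggplot(as_tibble(plane),
                  ggplot2::aes(x = .data$delta_effect, y = .data$delta_cost,
                               colour = .data$cost_effective)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::labs(
      title = sprintf("Cost-effectiveness plane: %s vs %s",
                      attr(plane, "strategy"), attr(plane, "reference")),
      x = "Incremental QALYs", y = "Incremental cost",
      colour = sprintf("Below WTP %s", format(wtp, big.mark = ","))
    ) +
    ggplot2::theme_minimal()
}

#' Plot cost-effectiveness acceptability curves
#'
#' Probability that each strategy has the highest net monetary benefit,
#' as a function of the willingness-to-pay threshold.
#'
#' @param object A `ceac_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ceac_result <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$wtp, y = .data$probability,
                               colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(title = "Cost-effectiveness acceptability curves",
                  x = "Willingness to pay per QALY",
                  y = "Probability cost-effective",
                  colour = "Strategy") +
    ggplot2::theme_minimal()
}

#' @export
plot.cohort_trace <- function(x, ...) print(autoplot.cohort_trace(x, ...))

#' @export
plot.tornado_result <- function(x, ...) print(autoplot.tornado_result(x, ...))

#' @export
plot.ceac_result <- function(x, ...) print(autoplot.ceac_result(x, ...))
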