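#' Define a Markov cohort model for one strategy
#'
#' Couples a transition matrix with the cohort's starting distribution,
#' horizon, discounting and the per-state values (utilities and costs)
#' accumulated while the cohort occupies each state.  Cycles are annual;
#' the default horizon is 5 cycles with costs and QALYs discounted at 5%
#' per year and half-cycle correction on.
#'
#' @param label Strategy name.
#' @param transitions A `transition_matrix` (see [transition_matrix()]).
#' @param init Initial occupancy vector (named by state or in state
#'   order); must sum to 1.  Default: the whole cohort starts in the
#'   stable-disease state.
#' @param n_cycles Number of annual cycles (default 5).
#' @param discount_rate Annual discount rate for costs and QALYs
#'   (default 0.05).
#' @param half_cycle Apply trapezoidal half-cycle correction (default
#'   `TRUE`).
#' @param utilities Named per-state utility weights in \[0, 1\]
#'   (death must be 0 unless deliberately overridden).
#' @param state_costs Named per-state per-cycle costs (currency).
#' @param intervention_cost One-off cost charged, undiscounted, at the
#'   first cycle (chemotherapy acquisition and administration).
#' @param cycle_length Cycle length in years (default 1; retained for
#'   completeness, QALYs scale linearly with it).
#' @return An object of class `model_spec`.
#' @examples
#' m <- transition_matrix(derive_transitions(acth_summary()))
#' model_spec("ACTH", m,
#'            utilities = c(stable = 0.74, remission = 0.85,
#'                          relapse = 0.5, death = 0),
#'            state_costs = c(stable = 1000, remission = 350,
#'                            relapse = 2200, death = 0),
#'            intervention_cost = 3112)
#' @export
model_spec <- function(label, transitions,
                       init = c(stable = 1, remission = 0, relapse = 0, death = 0),
                       n_cycles = 5L, discount_rate = 0.05, half_cycle = TRUE,
                       utilities, state_costs, intervention_cost = 0,
                       cycle_length = 1) {
  transitions <- validate_transition_matrix(unclass(transitions))
  states <- rownames(transitions)
  init <- align_state_values(init, states, "init")
  if (abs(sum(init) - 1) > 1e-10 || any(init < 0)) {
    abort("`init` must be a non-negative occupancy vector summing to 1.",
          class = "markovcea_model_definition")
  }
  if (!is.numeric(n_cycles) || n_cycles < 1) {
    abort("`n_cycles` must be >= 1.", class = "markovcea_model_definition")
  }
  if (discount_rate < 0) {
    abort("`discount_rate` must be >= 0.", class = "markovcea_model_definition")
  }
  utilities <- align_state_values(utilities, states, "utilities")
  if (any(utilities < 0 | utilities > 1)) {
    abort("`utilities` must lie in [0, 1].", class = "markovcea_model_definition")
  }
  state_costs <- align_state_values(state_costs, states, "state_costs")
  if (any(state_costs < 0)) {
    abort("`state_costs` must be non-negative.", class = "markovcea_model_definition")
  }
  structure(
    list(label = label, transitions = transitions, states = states,
         init = init, n_cycles = as.integer(n_cycles),
         discount_rate = discount_rate, half_cycle = isTRUE(half_cycle),
         utilities = utilities, state_costs = state_costs,
         intervention_cost = intervention_cost, cycle_length = cycle_length),
    class = "model_spec"
  )
}

# match a (possibly unnamed) per-state vector against the state ordering
align_state_values <- function(x, states, what) {
  x <- unlist(x)
  if (is.null(names(x))) {
    if (length(x) != length(states)) {
      abort(sprintf("`%s` must have one value per state.", what),
            class = "markovcea_model_definition")
    }
    return(setNames(as.numeric(x), states))
  }
  missing <- setdiff(states, names(x))
  if (length(missing)) {
    abort(sprintf("`%s` is missing states: %s.", what, paste(missing, collapse = ", ")),
          class = "markovcea_model_definition")
  }
  setNames(as.numeric(x[states]), states)
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s: %d states, %d annual cycles, discount %.1f%%, half-cycle %s\n",
              x$label, length(x$states), x$n_cycles, 100 * x$discount_rate,
              if (x$half_cycle) "on" else "off"))
  invisible(x)
}

#' Run the cohort model and return its trace
#'
#' Iterates the cohort distribution through the transition matrix:
#' `occupancy[t] = occupancy[t-1] %*% P` for `t = 1, ..., n_cycles`.  The
#' trace rows are checked to remain a probability distribution within
#' `1e-10` at every cycle.
#'
#' @param spec A [model_spec()].
#' @return A `cohort_trace`: a tibble with `cycle` = 0..n and one
#'   occupancy column per state; the half-cycle-corrected memberships and
#'   the spec are attached as attributes (`corrected`, `spec`).
#' @examples
#' m <- transition_matrix(derive_transitions(acth_summary()))
#' spec <- model_spec("ACTH", m,
#'                    utilities = c(stable = 0.74, remission = 0.85,
#'                                  relapse = 0.5, death = 0),
#'                    state_costs = c(stable = 0, remission = 0,
#'                                    relapse = 0, death = 0))
#' run_cohort(spec)
#' @export
run_cohort <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  P <- unclass(spec$transitions)
  n <- spec$n_cycles
  occ <- matrix(NA_real_, n + 1L, length(spec$states),
                dimnames = list(NULL, spec$states))
  occ[1L, ] <- spec$init
  for (t in seq_len(n)) {
    occ[t + 1L, ] <- occ[t, , drop = FALSE] %*% P
    if (abs(sum(occ[t + 1L, ]) - 1) > 1e-10) {
      abort(sprintf("occupancy mass not conserved at cycle %d.", t),
            class = "markovcea_model_definition")
    }
  }
  trace <- as_tibble(as.data.frame(occ))
  trace <- dplyr::bind_cols(tibble(cycle = 0:n), trace)
  corrected <- half_cycle_memberships(occ)
  structure(trace, corrected = corrected, spec = spec,
            class = c("cohort_trace", class(trace)))
}

half_cycle_memberships <- function(occ) {
  n <- nrow(occ) - 1L
  half <- (occ[seq_len(n), , drop = FALSE] + occ[seq_len(n) + 1L, , drop = FALSE]) / 2
  out <- as_tibble(as.data.frame(half))
  dplyr::bind_cols(tibble(cycle = seq_len(n)), out)
}

#' Half-cycle-corrected state memberships
#'
#' Trapezoidal correction: the membership credited to cycle `t` is the
#' average of the occupancy at the start and end of the cycle,
#' `(occupancy[t-1] + occupancy[t]) / 2`.
#'
#' @param trace A `cohort_trace` from [run_cohort()], or a numeric matrix
#'   of occupancies with one row per cycle boundary (0..n).
#' @return A tibble with `cycle` = 1..n and corrected membership per state.
#' @export
half_cycle_correct <- function(trace) {
  if (inherits(trace, "cohort_trace")) return(attr(trace, "corrected"))
  if (is.matrix(trace)) {
    if (nrow(trace) < 2L) abort("need at least one cycle to correct.")
    return(half_cycle_memberships(trace))
  }
  abort("`trace` must be a cohort_trace or an occupancy matrix.")
}

#' Per-cycle discount factor
#'
#' `1 / (1 + rate)^(t - 1)`: the first cycle is undiscounted, matching the
#' convention that up-front chemotherapy costs are charged at face value.
#'
#' @param rate Annual discount rate (>= 0).
#' @param t Cycle index (1-based); vectorised.
#' @return Discount factor(s) in (0, 1].
#' @examples
#' discount_factor(0.05, 1:5)
#' @export
discount_factor <- function(rate, t) {
  stopifnot(rate >= 0, all(t >= 1))
  1 / (1 + rate)^(t - 1)
}

#' Accumulate a discounted per-state value over the cohort trace
#'
#' Computes `sum_t df(rate, t) * sum_s membership[t, s] * values[s]`, plus
#' an undiscounted one-off amount at cycle 1.  With the spec's utilities
#' and `one_off = 0` this is the discounted QALY total; with state costs
#' and `one_off = intervention_cost` it is the discounted cost total.
#' Membership is half-cycle corrected when `half_cycle` is on, otherwise
#' the end-of-cycle occupancy is used.
#'
#' @param trace A `cohort_trace`.
#' @param values Named per-state values; must cover every state.
#' @param rate Discount rate; defaults to the spec the trace was run with.
#' @param one_off One-off amount added at cycle 1 (undiscounted).
#' @param half_cycle Override the spec's half-cycle flag.
#' @return A single discounted total.
#' @export
accumulate_value <- function(trace, values, rate = NULL, one_off = 0,
                             half_cycle = NULL) {
  stopifnot(inherits(trace, "cohort_trace"))
  spec <- attr(trace, "spec")
  rate <- rate %||% spec$discount_rate
  half_cycle <- half_cycle %||% spec$half_cycle
  values <- align_state_values(values, spec$states, "values")
  n <- spec$n_cycles
  if (half_cycle) {
    mem <- as.matrix(attr(trace, "corrected")[, spec$states, drop = FALSE])
  } else {
    mem <- as.matrix(trace[-1L, spec$states, drop = FALSE])
  }
  df <- discount_factor(rate, seq_len(n))
  sum(df * as.numeric(mem %*% values)) * spec$cycle_length + one_off
}

#' Evaluate a strategy: discounted cost and QALY totals
#'
#' Runs the cohort and accumulates discounted QALYs (from the utilities)
#' and discounted costs (state costs plus the one-off intervention cost at
#' cycle 1).
#'
#' @param spec A [model_spec()].
#' @return A one-row tibble: `label`, `intervention_cost`,
#'   `state_cost` (discounted health-system component), `cost` (total),
#'   `effect` (QALYs); the trace is attached as attribute `trace`.
#' @export
evaluate_strategy <- function(spec) {
  trace <- run_cohort(spec)
  effect <- accumulate_value(trace, spec$utilities)
  state_cost <- accumulate_value(trace, spec$state_costs)
  out <- tibble(
    label = spec$label,
    intervention_cost = spec$intervention_cost,
    state_cost = state_cost,
    cost = state_cost + spec$intervention_cost,
    effect = effect
  )
  attr(out, "trace") <- trace
  out
}

#' Per-cycle trace table for export
#'
#' One row per cycle with the raw and half-cycle-corrected occupancy per
#' state, the discount factor, and the (discounted) cycle cost and QALY
#' contributions.
#'
#' @param trace A `cohort_trace`.
#' @return A tibble with `n_cycles` rows.
#' @export
trace_table <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  spec <- attr(trace, "spec")
  states <- spec$states
  n <- spec$n_cycles
  raw <- as.matrix(trace[-1L, states, drop = FALSE])
  corr <- as.matrix(attr(trace, "corrected")[, states, drop = FALSE])
  mem <- if (spec$half_cycle) corr else raw
  df <- discount_factor(spec$discount_rate, seq_len(n))
  out <- tibble(cycle = seq_len(n))
  for (s in states) out[[paste0("occupancy_", s)]] <- raw[, s]
  for (s in states) out[[paste0("corrected_", s)]] <- corr[, s]
  out$discount_factor <- df
  out$cycle_cost <- df * as.numeric(mem %*% spec$state_costs)
  out$cycle_qaly <- df * as.numeric(mem %*% spec$utilities) * spec$cycle_length
  out$cycle_cost[1] <- out$cycle_cost[1] + spec$intervention_cost
  out
}
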