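#' Enumerate the sensitivity parameters of a configuration
#'
#' Builds the one-way / PSA parameter table: for each arm the seven
#' transition-probability cells (the four free row parameters plus the
#' three stay probabilities, which are varied through their complements),
#' the per-state utilities, and the cost parameters.  Probabilities and
#' utilities carry beta distributions; costs carry gamma.  Ranges are
#' `estimate * (1 +/- fraction)`, capped at 1 for probabilities and
#' utilities.
#'
#' The `free` column marks parameters that are sampled in the PSA: stay
#' probabilities are complements of sampled cells and are excluded there
#' (sampling both a probability and its complement would double-count the
#' row's uncertainty), but remain available to one-way analysis so every
#' published table row can be varied.
#'
#' @param config Configuration list.
#' @param fraction Range half-width; defaults to the config's
#'   `psa$fraction`.
#' @return A tibble: `name`, `kind` (`transition`, `stay`, `utility`,
#'   `cost`), `estimate`, `lo`, `hi`, `family`, `free`.
#' @export
sa_parameters <- function(config, fraction = NULL) {
  fraction <- fraction %||% config$psa$fraction %||% 0.2
  states <- unlist(config$states)
  rows <- list()
  for (arm in config$arms) {
    lab <- arm$label
    tab <- derivation_table_for_arm(arm, config, fraction)
    rows[[length(rows) + 1L]] <- tibble(
      name = paste0(lab, ".", tab$param),
      kind = ifelse(tab$param %in% c("p_ss", "p_rr", "p_pp"), "stay", "transition"),
      estimate = tab$estimate, lo = tab$lo, hi = tab$hi,
      family = "beta",
      free = !tab$param %in% c("p_ss", "p_rr", "p_pp")
    )
    costs <- unlist(arm$state_costs)
    costs <- costs[setdiff(names(costs), "death")]
    cost_rng <- sa_range(unname(costs), fraction, cap = c(0, Inf))
    rows[[length(rows) + 1L]] <- tibble(
      name = c(paste0(lab, ".cost_", names(costs)), paste0(lab, ".intervention_cost")),
      kind = "cost",
      estimate = c(unname(costs), arm$intervention_cost %||% 0),
      lo = c(cost_rng$lo, max(0, (arm$intervention_cost %||% 0) * (1 - fraction))),
      hi = c(cost_rng$hi, (arm$intervention_cost %||% 0) * (1 + fraction)),
      family = "gamma",
      free = TRUE
    )
  }
  u <- unlist(config$utilities)
  u <- u[setdiff(names(u), "death")]
  u_rng <- sa_range(unname(u), fraction, cap = c(0, 1))
  rows[[length(rows) + 1L]] <- tibble(
    name = paste0("utility.", names(u)),
    kind = "utility",
    estimate = unname(u), lo = u_rng$lo, hi = u_rng$hi,
    family = "beta", free = TRUE
  )
  purrr::list_rbind(rows)
}

# full derivation table (7 rows) for one arm, honoring direct probabilities
derivation_table_for_arm <- function(arm, config, fraction) {
  if (is.null(arm$probabilities)) {
    s <- arm$summary
    return(derive_transitions(
      clinical_summary(arm$label, s$rr, s$os_median, s$ttp_median, s$dor_median,
                       rp_digits = s$rp_digits %||% 3L),
      rounding = config$rounding %||% "printed",
      sa_fraction = fraction,
      exit_factor = config$constants$exit_factor %||% 0.75,
      response_divisor = config$constants$response_divisor %||% 3
    ))
  }
  p <- arm$probabilities
  est <- c(p_ss = 1 - p$p_sr - p$p_sp, p_sr = p$p_sr, p_sp = p$p_sp,
           p_rr = 1 - p$p_rp, p_rp = p$p_rp, p_pp = 1 - p$p_pd, p_pd = p$p_pd)
  rng <- sa_range(unname(est), fraction, cap = c(0, 1))
  tibble(arm = arm$label,
         from = c("stable", "stable", "stable", "remission", "remission",
                  "relapse", "relapse"),
         to = c("stable", "remission", "relapse", "remission", "relapse",
                "relapse", "death"),
         param = names(est), estimate = unname(est),
         lo = rng$lo, hi = rng$hi, distribution = "beta")
}

# incremental NMB of the first-listed strategy versus the second at wtp
inmb_of <- function(evaluation, wtp) {
  n <- nmb(evaluation$outcomes, wtp = wtp)
  n$nmb[1L] - n$nmb[2L]
}

sa_output_value <- function(evaluation, output, wtp) {
  switch(output,
         inmb = inmb_of(evaluation, wtp),
         icer = evaluation$comparison$icer,
         abort("`output` must be 'inmb' or 'icer'."))
}

#' One-way sensitivity analysis for a single parameter
#'
#' Re-runs the full pipeline with the parameter set to its lower and
#' upper bound (all other parameters at their best estimates) and reports
#' the swing of the chosen output: the incremental net monetary benefit
#' of the first strategy versus the second at `wtp` (default), or the
#' ICER.
#'
#' @param config Configuration list.
#' @param param A parameter name or a one-row slice of
#'   [sa_parameters()].
#' @param output `"inmb"` (default) or `"icer"`.
#' @param wtp Willingness-to-pay for the NMB output (default 20,000, the
#'   acceptability-curve threshold).
#' @param params Parameter table to resolve names against.
#' @return A one-row tibble: `name`, `lo`, `hi`, `out_lo`, `out_hi`,
#'   `out_base`, `swing`.
#' @export
one_way <- function(config, param, output = c("inmb", "icer"), wtp = 20000,
                    params = sa_parameters(config)) {
  output <- match.arg(output)
  if (is.character(param)) {
    param <- params[params$name == param, ]
    if (nrow(param) != 1L) abort("unknown sensitivity parameter.")
  }
  base <- evaluate_config(config)
  at <- function(value) {
    ev <- evaluate_config(config, overrides = setNames(value, param$name))
    sa_output_value(ev, output, wtp)
  }
  out_lo <- at(param$lo)
  out_hi <- at(param$hi)
  tibble(
    name = param$name, lo = param$lo, hi = param$hi,
    out_lo = out_lo, out_hi = out_hi,
    out_base = sa_output_value(base, output, wtp),
    swing = abs(out_hi - out_lo)
  )
}

#' Tornado analysis: one-way swings for every parameter, ordered
#'
#' Runs [one_way()] for each parameter and sorts by swing (descending,
#' ties broken alphabetically by name for determinism).  `cumulative`
#' optionally truncates the list to the smallest set of parameters
#' covering that share of the total swing (e.g. 0.99).
#'
#' @param config Configuration list.
#' @param params Parameter table (default: all of [sa_parameters()]).
#' @param output,wtp Passed to [one_way()].
#' @param cumulative Cumulative swing share to retain, in (0, 1\].
#' @return A `tornado_result` tibble (the [one_way()] rows, ordered).
#' @export
tornado <- function(config, params = sa_parameters(config),
                    output = c("inmb", "icer"), wtp = 20000, cumulative = 1) {
  output <- match.arg(output)
  stopifnot(nrow(params) >= 1L, cumulative > 0, cumulative <= 1)
  res <- purrr::map(seq_len(nrow(params)),
                    \(i) one_way(config, params[i, ], output = output, wtp = wtp)) |>
    purrr::list_rbind() |>
    dplyr::arrange(dplyr::desc(.data$swing), .data$name)
  if (cumulative < 1) {
    total <- sum(res$swing)
    if (total > 0) {
      covered <- cumsum(res$swing) / total
      keep <- c(TRUE, utils::head(covered, -1) < cumulative)
      res <- res[keep, ]
    }
  }
  structure(res, output = output, wtp = wtp,
            class = c("tornado_result", class(res)))
}

#' Probabilistic sensitivity analysis (second-order Monte Carlo)
#'
#' Fits a distribution to every free parameter (beta for probabilities
#' and utilities, gamma for costs, treating the range as a central 95%
#' interval; see [fit_beta()] / [fit_gamma()]), draws `n_sims` parameter
#' sets, and re-evaluates the deterministic cohort model for both arms at
#' each draw.  Stay probabilities are recomputed as complements of the
#' sampled cells; if a sampled stable row exceeds total probability 1 its
#' free parameters are rescaled proportionally (the count of such events
#' is reported once).
#'
#' @param config Configuration list.
#' @param n_sims Number of parameter draws (default from the config,
#'   1000).
#' @param seed RNG seed; the same `(seed, n_sims)` reproduces draws
#'   exactly.
#' @param fraction Range half-width (default from the config); 0 makes
#'   every distribution a point mass and reproduces the base case.
#' @return A `psa_result` tibble with one row per draw: `sim`, per-arm
#'   `cost_*` / `effect_*`, `delta_cost`, `delta_effect` (first vs second
#'   strategy).  Attributes: `param_draws` (matrix), `labels`, `seed`,
#'   `n_rebalanced`, `base` (deterministic evaluation), `config`.
#' @export
run_psa <- function(config, n_sims = NULL, seed = NULL, fraction = NULL) {
  n_sims <- as.integer(n_sims %||% config$psa$n_sims %||% 1000L)
  stopifnot(n_sims >= 1L)
  fraction <- fraction %||% config$psa$fraction %||% 0.2
  if (!is.null(seed)) withr::local_seed(seed)

  params <- sa_parameters(config, fraction = fraction)
  params <- params[params$free, ]
  fits <- purrr::pmap(params[, c("estimate", "lo", "hi", "family")],
                      function(estimate, lo, hi, family) {
                        if (family == "beta") {
                          if (estimate <= 0 || estimate >= 1 || lo == hi) {
                            structure(list(dist = "point", value = estimate,
                                           mean = estimate), class = "param_dist")
                          } else {
                            fit_beta(estimate, lo, hi)
                          }
                        } else {
                          if (estimate <= 0 || lo == hi) {
                            structure(list(dist = "point", value = estimate,
                                           mean = estimate), class = "param_dist")
                          } else {
                            fit_gamma(estimate, lo, hi)
                          }
                        }
                      })
  draws <- vapply(fits, sample_dist, numeric(n_sims), n = n_sims)
  if (n_sims == 1L) draws <- matrix(draws, nrow = 1L)
  colnames(draws) <- params$name

  labels <- purrr::map_chr(config$arms, "label")
  n_rebalanced <- 0L
  rows <- vector("list", n_sims)
  for (i in seq_len(n_sims)) {
    ev <- evaluate_config(config, overrides = draws[i, ])
    n_rebalanced <- n_rebalanced + ev$rebalanced
    o <- ev$outcomes
    row <- tibble(sim = i)
    for (j in seq_along(labels)) {
      row[[paste0("cost_", labels[j])]] <- o$cost[j]
      row[[paste0("effect_", labels[j])]] <- o$effect[j]
    }
    row$delta_cost <- ev$comparison$delta_cost
    row$delta_effect <- ev$comparison$delta_effect
    rows[[i]] <- row
  }
  out <- purrr::list_rbind(rows)
  if (n_rebalanced > 0L) {
    inform(sprintf("PSA: %d sampled stable row(s) exceeded probability 1 and were rescaled.",
                   n_rebalanced))
  }
  structure(out,
            param_draws = draws, labels = labels, seed = seed,
            n_rebalanced = n_rebalanced, base = evaluate_config(config),
            config = config,
            class = c("psa_result", class(out)))
}

#' Percentile uncertainty interval of the PSA draws
#'
#' 95% interval from the 2.5th and 97.5th percentile ranks of the draws.
#'
#' @param psa A `psa_result`.
#' @param probs Percentile pair.
#' @return A tibble: `quantity`, `mean`, `lo`, `hi`.
#' @export
psa_interval <- function(psa, probs = c(0.025, 0.975)) {
  stopifnot(inherits(psa, "psa_result"))
  summarise_one <- function(x, quantity) {
    q <- quantile(x, probs, type = 1, names = FALSE)
    tibble(quantity = quantity, mean = mean(x), lo = q[1], hi = q[2])
  }
  dplyr::bind_rows(
    summarise_one(psa$delta_cost, "delta_cost"),
    summarise_one(psa$delta_effect, "delta_effect")
  )
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay threshold, the fraction of PSA draws in
#' which each strategy has the highest net monetary benefit (ties broken
#' toward the cheaper strategy, then first-listed).  Fractions sum to 1
#' at every threshold.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Thresholds; default from the attached config.
#' @return A `ceac_result` tibble: `wtp`, `strategy`, `probability`.
#' @export
ceac <- function(psa, wtp_grid = NULL) {
  stopifnot(inherits(psa, "psa_result"), nrow(psa) >= 1L)
  config <- attr(psa, "config")
  wtp_grid <- wtp_grid %||% ceac_grid(config)
  labels <- attr(psa, "labels")
  costs <- as.matrix(as_tibble(psa)[, paste0("cost_", labels)])
  effects <- as.matrix(as_tibble(psa)[, paste0("effect_", labels)])
  out <- purrr::map(wtp_grid, function(l) {
    benefit <- l * effects - costs
    pick <- integer(nrow(benefit))
    for (r in seq_len(nrow(benefit))) {
      best <- which(benefit[r, ] == max(benefit[r, ]))
      # ties toward the cheaper strategy, then first-listed
      if (length(best) > 1L) best <- best[order(costs[r, best])]
      pick[r] <- best[1L]
    }
    tibble(wtp = l, strategy = labels,
           probability = as.numeric(tabulate(pick, nbins = length(labels))) / nrow(psa))
  }) |> purrr::list_rbind()
  structure(out, labels = labels, class = c("ceac_result", class(out)))
}

#' Cost-effectiveness plane
#'
#' Labels each PSA draw by quadrant of the incremental (effect, cost)
#' plane for `strategy` versus `reference` and by whether it falls on or
#' below the willingness-to-pay ray (`delta_cost <= wtp * delta_effect`;
#' points on the ray count as cost-effective).  Quadrant I: more
#' effective and more costly; II: less effective, more costly; III: less
#' effective, less costly; IV: more effective and cheaper (dominant).
#'
#' @param psa A `psa_result`.
#' @param wtp Willingness-to-pay ray (default 20,000).
#' @param strategy,reference Strategy labels; default: second listed
#'   versus first (the published plane plots TCH against AC-TH).
#' @return A `ce_plane_result` tibble: `sim`, `delta_effect`,
#'   `delta_cost`, `quadrant`, `cost_effective`.
#' @export
ce_plane <- function(psa, wtp = 20000, strategy = NULL, reference = NULL) {
  stopifnot(inherits(psa, "psa_result"), nrow(psa) >= 1L)
  labels <- attr(psa, "labels")
  strategy <- strategy %||% labels[2L]
  reference <- reference %||% labels[1L]
  stopifnot(strategy %in% labels, reference %in% labels)
  de <- psa[[paste0("effect_", strategy)]] - psa[[paste0("effect_", reference)]]
  dc <- psa[[paste0("cost_", strategy)]] - psa[[paste0("cost_", reference)]]
  quadrant <- dplyr::case_when(
    de >= 0 & dc > 0 ~ "I",
    de < 0 & dc > 0 ~ "II",
    de < 0 & dc <= 0 ~ "III",
    TRUE ~ "IV"
  )
  out <- tibble(
    sim = psa$sim, delta_effect = de, delta_cost = dc,
    quadrant = quadrant,
    cost_effective = dc <= wtp * de
  )
  structure(out, wtp = wtp, strategy = strategy, reference = reference,
            class = c("ce_plane_result", class(out)))
}
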