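#' Run the full analysis pipeline and write its outputs
#'
#' Executes derivation -> cohort -> incremental analysis -> one-way
#' (tornado) -> PSA -> CEAC from a configuration and writes plain-CSV
#' outputs plus a JSON run manifest to `output_dir`:
#'
#' * `derivation.csv` — per-arm transition table (estimate, SA range,
#'   distribution), with a `printed` column rounded to published
#'   precision
#' * `trace_<arm>.csv` — per-cycle raw and corrected occupancy, discount
#'   factor, cycle cost and QALY
#' * `results.csv` — per-strategy totals, deltas and ICER
#' * `tornado.csv` — ordered one-way swings
#' * `psa_draws.csv`, `ceac.csv` — PSA scatter and acceptability curves
#'   (omitted when `psa = FALSE` or `n_sims = 0`)
#' * `manifest.json` — seed, package version, config hash, file list
#'
#' @param config Configuration list (see [load_config()]).
#' @param output_dir Directory for outputs (created if needed).
#' @param seed RNG seed for the PSA.
#' @param n_sims PSA draws; 0 disables the PSA stage.
#' @param psa Run the PSA/CEAC stage.
#' @param tornado_cumulative Cumulative swing share retained in the
#'   tornado table.
#' @return Invisibly, a list with every intermediate result
#'   (`derivation`, `traces`, `outcomes`, `comparison`, `nmb`,
#'   `tornado`, `psa`, `ceac`, `manifest`).
#' @export
run_pipeline <- function(config, output_dir, seed = 1L,
                         n_sims = config$psa$n_sims %||% 1000L,
                         psa = TRUE, tornado_cumulative = 1) {
  config <- validate_config(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  emit <- function(x, name) {
    path <- file.path(output_dir, name)
    readr::write_csv(x, path)
    files <<- c(files, name)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            parent = e)
    })
  }

  derivation <- stage("derive", {
    tabs <- purrr::map(config$arms, derivation_table_for_arm, config = config,
                       fraction = config$psa$fraction %||% 0.2) |>
      purrr::list_rbind()
    tabs$printed <- round(tabs$estimate, 3L)
    tabs
  })
  emit(derivation, "derivation.csv")
  inform(sprintf("derive: %d transition parameters across %d arms.",
                 nrow(derivation), length(config$arms)))

  models <- stage("cohort", build_models(config))
  traces <- purrr::map(models$specs, run_cohort)
  names(traces) <- purrr::map_chr(models$specs, "label")
  for (lab in names(traces)) {
    emit(trace_table(traces[[lab]]), sprintf("trace_%s.csv", lab))
  }

  econ <- stage("econ", evaluate_config(config))
  res_tab <- results_table(econ$outcomes, econ$comparison)
  emit(res_tab, "results.csv")
  nmb_tab <- nmb(econ$outcomes, wtp = config$thresholds$nmb_wtp %||% 34240)
  inform(sprintf("econ: delta cost %.0f, delta effect %.3f QALYs, %s.",
                 econ$comparison$delta_cost, econ$comparison$delta_effect,
                 if (econ$comparison$dominance == "none") {
                   sprintf("ICER %.0f", econ$comparison$icer)
                 } else {
                   "dominance (see NMB)"
                 }))

  torn <- stage("owsa", tornado(config, wtp = config$thresholds$ceac_wtp %||% 20000,
                                cumulative = tornado_cumulative))
  emit(as_tibble(torn), "tornado.csv")

  psa_res <- NULL
  ceac_res <- NULL
  if (isTRUE(psa) && n_sims > 0) {
    psa_res <- stage("psa", run_psa(config, n_sims = n_sims, seed = seed))
    emit(as_tibble(psa_res), "psa_draws.csv")
    ceac_res <- stage("ceac", ceac(psa_res))
    emit(as_tibble(ceac_res), "ceac.csv")
  }

  manifest <- list(
    package = "markovcea",
    version = as.character(packageVersion("markovcea")),
    seed = seed,
    n_sims = if (isTRUE(psa)) n_sims else 0L,
    config_hash = rlang::hash(unclass(config)),
    files = files,
    defaults = list(
      n_cycles = config$n_cycles, discount_rate = config$discount_rate,
      half_cycle = config$half_cycle, rounding = config$rounding,
      nmb_wtp = config$thresholds$nmb_wtp, ceac_wtp = config$thresholds$ceac_wtp,
      psa_fraction = config$psa$fraction
    )
  )
  manifest_path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)

  invisible(list(derivation = derivation, traces = traces,
                 outcomes = econ$outcomes, comparison = econ$comparison,
                 nmb = nmb_tab, tornado = torn, psa = psa_res, ceac = ceac_res,
                 manifest = manifest))
}
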