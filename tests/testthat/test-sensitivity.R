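test_that("sa_parameters enumerates transitions, utilities and costs", {
  cfg <- test_config()
  params <- sa_parameters(cfg)
  expect_true(all(c("ACTH.p_sr", "TCH.p_rr", "utility.relapse",
                    "ACTH.cost_relapse", "TCH.intervention_cost") %in% params$name))
  expect_true(all(params$family[params$kind == "cost"] == "gamma"))
  expect_true(all(params$family[params$kind != "cost"] == "beta"))
  # stay probabilities are one-way-only, not sampled
  expect_false(any(params$free[params$kind == "stay"]))
  expect_true(all(params$lo <= params$estimate & params$estimate <= params$hi))
})

test_that("a degenerate range produces zero swing", {
  cfg <- test_config()
  params <- sa_parameters(cfg)
  p <- params[params$name == "ACTH.p_sr", ]
  p$lo <- p$estimate
  p$hi <- p$estimate
  res <- one_way(cfg, p)
  expect_equal(res$swing, 0)
})

test_that("arm-symmetric parameters have zero incremental swing", {
  cfg <- symmetric_config()
  res <- one_way(cfg, "utility.remission")
  expect_equal(res$swing, 0, tolerance = 1e-9)
})

test_that("one-way bounds agree with hand-edited direct-probability configs", {
  cfg <- test_config()
  res <- one_way(cfg, "ACTH.p_sr")
  # independently rebuild the lower-bound scenario with direct probabilities
  direct <- cfg
  direct$arms[[1]]$summary <- NULL
  direct$arms[[1]]$probabilities <- list(p_sr = 0.1944, p_sp = 0.356,
                                         p_rp = 0.089, p_pd = 0.014)
  ev <- evaluate_config(direct)
  n <- nmb(ev$outcomes, wtp = 20000)
  expect_equal(res$out_lo, n$nmb[1] - n$nmb[2], tolerance = 1e-9)
})

test_that("varying a stay probability adjusts its complement row", {
  cfg <- test_config()
  models <- build_models(cfg, overrides = c(ACTH.p_rr = 0.8))
  m <- models$specs[[1]]$transitions
  expect_equal(unname(m["remission", "relapse"]), 0.2)
  models <- build_models(cfg, overrides = c(ACTH.p_ss = 0.5))
  m <- models$specs[[1]]$transitions
  expect_equal(unname(m["stable", "stable"]), 0.5)
  # sr:sp proportions preserved
  expect_equal(unname(m["stable", "remission"] / m["stable", "relapse"]),
               0.243 / 0.356)
  # impossible stay values are rejected
  expect_error(build_models(cfg, overrides = c(ACTH.p_rr = 1.2)),
               class = "markovcea_infeasible_scenario")
})

test_that("tornado ordering is deterministic and permutation invariant", {
  cfg <- test_config()
  params <- sa_parameters(cfg)
  params <- params[params$kind %in% c("transition", "stay"), ]
  t1 <- tornado(cfg, params)
  withr::with_seed(5, {
    t2 <- tornado(cfg, params[sample(nrow(params)), ])
  })
  expect_identical(t1$name, t2$name)
  expect_true(all(diff(t1$swing) <= 1e-12))

  # a single parameter yields a single row
  expect_identical(nrow(tornado(cfg, params[1, ])), 1L)

  # zero-swing parameters sort last
  p0 <- params[params$name == "ACTH.p_sr", ]
  p0$lo <- p0$estimate; p0$hi <- p0$estimate
  p0$name <- "zzz.degenerate"
  t3 <- tornado(cfg, dplyr::bind_rows(p0, params[2, ]))
  expect_identical(t3$name[nrow(t3)], "zzz.degenerate")

  # cumulative truncation keeps the widest bars
  t4 <- tornado(cfg, params, cumulative = 0.5)
  expect_lt(nrow(t4), nrow(t1))
  expect_identical(t4$name, t1$name[seq_len(nrow(t4))])
})

test_that("the transition-probability tornado is led by remission-row parameters", {
  cfg <- test_config()
  params <- sa_parameters(cfg)
  params <- params[params$kind %in% c("transition", "stay"), ]
  top5 <- tornado(cfg, params)$name[1:5]
  expect_true(any(top5 %in% c("TCH.p_rr", "TCH.p_rp", "TCH.p_sr")))
})

test_that("point-mass PSA reproduces the deterministic base case", {
  cfg <- test_config()
  psa <- run_psa(cfg, n_sims = 3, seed = 1, fraction = 0)
  base <- evaluate_config(cfg)
  expect_equal(unique(psa$delta_cost), base$comparison$delta_cost)
  expect_equal(unique(psa$delta_effect), base$comparison$delta_effect)
})

test_that("PSA draws are reproducible under a fixed seed", {
  cfg <- test_config()
  a <- run_psa(cfg, n_sims = 25, seed = 99)
  b <- run_psa(cfg, n_sims = 25, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "param_draws"), attr(b, "param_draws"))
  c2 <- run_psa(cfg, n_sims = 25, seed = 100)
  expect_false(identical(a$delta_cost, c2$delta_cost))
})

test_that("the PSA percentile interval widens with the range fraction", {
  cfg <- test_config()
  narrow <- run_psa(cfg, n_sims = 150, seed = 21, fraction = 0.1)
  wide <- run_psa(cfg, n_sims = 150, seed = 21, fraction = 0.3)
  in_n <- psa_interval(narrow)
  in_w <- psa_interval(wide)
  expect_true(all(in_w$hi - in_w$lo > in_n$hi - in_n$lo))
})

test_that("CEAC probabilities sum to 1 and follow NMB maximisation draw-by-draw", {
  cfg <- test_config()
  psa <- run_psa(cfg, n_sims = 100, seed = 31)
  grid <- c(0, 20000, 34240, 60000, 1e6)
  cc <- ceac(psa, grid)
  sums <- dplyr::summarise(dplyr::group_by(cc, wtp), s = sum(probability))
  expect_equal(sums$s, rep(1, length(grid)))
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))

  labels <- attr(psa, "labels")
  for (l in grid) {
    hand <- vapply(seq_len(nrow(psa)), function(i) {
      ben <- vapply(labels, function(s) {
        l * psa[[paste0("effect_", s)]][i] - psa[[paste0("cost_", s)]][i]
      }, 0)
      labels[which.max(ben)]
    }, "")
    for (s in labels) {
      expect_equal(cc$probability[cc$wtp == l & cc$strategy == s],
                   mean(hand == s))
    }
  }

  # lambda = 0: acceptability is the fraction of strictly cheaper draws
  cheaper <- mean(psa$cost_TCH < psa$cost_ACTH)
  expect_equal(cc$probability[cc$wtp == 0 & cc$strategy == "TCH"], cheaper)
  # very large lambda: acceptability approaches the fraction with more QALYs
  better <- mean(psa$effect_TCH > psa$effect_ACTH)
  expect_equal(cc$probability[cc$wtp == 1e6 & cc$strategy == "TCH"], better)
})

test_that("CEAC agrees with the ICER-threshold rule on undominated draws", {
  cfg <- test_config()
  psa <- run_psa(cfg, n_sims = 100, seed = 77)
  lambda <- 20000
  cc <- ceac(psa, lambda)
  pick_icer <- vapply(seq_len(nrow(psa)), function(i) {
    cmp <- incremental(strategy_outcome("ACTH", psa$cost_ACTH[i], psa$effect_ACTH[i]),
                       strategy_outcome("TCH", psa$cost_TCH[i], psa$effect_TCH[i]))
    if (cmp$dominance == "a_dominates") return("ACTH")
    if (cmp$dominance == "b_dominates") return("TCH")
    if (!cmp$icer_defined) return(if (cmp$delta_cost < 0) "ACTH" else "TCH")
    if (cmp$delta_effect > 0) {
      if (cmp$icer < lambda) "ACTH" else "TCH"
    } else {
      if (cmp$icer > lambda) "ACTH" else "TCH"
    }
  }, "")
  expect_equal(cc$probability[cc$strategy == "ACTH"], mean(pick_icer == "ACTH"))
})

test_that("the CE plane labels quadrants and the WTP ray correctly", {
  cfg <- test_config()
  psa <- run_psa(cfg, n_sims = 40, seed = 13)
  plane <- ce_plane(psa, wtp = 20000)
  expect_identical(nrow(plane), 40L)
  expect_true(all(plane$quadrant %in% c("I", "II", "III", "IV")))
  expect_identical(sum(table(plane$quadrant)), 40L)
  # manual check of the ray rule
  expect_equal(plane$cost_effective,
               plane$delta_cost <= 20000 * plane$delta_effect)

  # hand-built draws: dominant point in quadrant IV, on-ray point cost-effective
  fake <- psa[1:2, ]
  fake$cost_TCH <- fake$cost_ACTH + c(-5, 20000)
  fake$effect_TCH <- fake$effect_ACTH + c(1, 1)
  for (a in c("param_draws", "labels", "config", "base")) {
    attr(fake, a) <- attr(psa, a)
  }
  class(fake) <- class(psa)
  plane2 <- ce_plane(fake, wtp = 20000)
  expect_identical(plane2$quadrant, c("IV", "I"))
  expect_true(all(plane2$cost_effective))
})

test_that("scenario toggles move totals in the predictable direction", {
  cfg <- test_config()
  discounted <- evaluate_config(cfg)
  cfg0 <- cfg
  cfg0$discount_rate <- 0
  undiscounted <- evaluate_config(cfg0)
  expect_true(all(undiscounted$outcomes$cost >= discounted$outcomes$cost))
  expect_true(all(undiscounted$outcomes$effect >= discounted$outcomes$effect))
})
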