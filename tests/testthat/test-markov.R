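test_that("one- and two-cycle occupancies match hand-computed products", {
  spec <- acth_spec()
  tr <- run_cohort(spec)
  expect_equal(unlist(tr[tr$cycle == 1, c("stable", "remission", "relapse", "death")]),
               c(stable = 0.401, remission = 0.243, relapse = 0.356, death = 0))
  # death after two cycles: only path is stable -> relapse -> death
  expect_equal(tr$death[tr$cycle == 2], 0.356 * 0.014)
  # half-cycle corrected death membership for cycle 2
  corr <- half_cycle_correct(tr)
  expect_equal(corr$death[corr$cycle == 2], (0 + 0.356 * 0.014) / 2)
})

test_that("identity transitions leave the cohort unchanged", {
  s <- markov_states <- c("stable", "remission", "relapse", "death")
  m <- validate_transition_matrix(diag(4) |> `dimnames<-`(list(s, s)))
  spec <- model_spec("static", m, init = c(0.4, 0.3, 0.2, 0.1),
                     utilities = base_utilities(),
                     state_costs = c(stable = 0, remission = 0, relapse = 0, death = 0))
  tr <- run_cohort(spec)
  for (t in 0:5) {
    expect_equal(unlist(tr[tr$cycle == t, s]),
                 c(stable = 0.4, remission = 0.3, relapse = 0.2, death = 0.1))
  }
  # constant trace: corrected memberships equal the occupancy
  corr <- half_cycle_correct(tr)
  expect_equal(corr$stable, rep(0.4, 5))
})

test_that("occupancy is conserved and death is monotone for random chains", {
  withr::with_seed(42, {
    for (i in 1:25) {
      m <- random_transition_matrix()
      spec <- model_spec("rand", m, utilities = base_utilities(),
                         state_costs = c(stable = 1, remission = 1,
                                         relapse = 1, death = 0),
                         n_cycles = 10)
      tr <- run_cohort(spec)
      sums <- rowSums(as.matrix(tr[, spec$states]))
      expect_true(all(abs(sums - 1) < 1e-10))
      expect_true(all(diff(tr$death) >= -1e-12))
    }
  })
})

test_that("half-cycle membership is the trapezoid of adjacent occupancies", {
  # a state emptying in one cycle is credited half a cycle
  occ <- matrix(c(1, 0, 0, 0,
                  0, 1, 0, 0), nrow = 2, byrow = TRUE,
                dimnames = list(NULL, c("stable", "remission", "relapse", "death")))
  corr <- half_cycle_correct(occ)
  expect_equal(corr$stable, 0.5)
  expect_equal(corr$remission, 0.5)
})

test_that("half-cycle-corrected totals lie between boundary-counted totals", {
  withr::with_seed(7, {
    for (i in 1:10) {
      m <- random_transition_matrix()
      spec <- model_spec("rand", m, utilities = base_utilities(),
                         state_costs = c(stable = 2, remission = 1,
                                         relapse = 5, death = 0),
                         discount_rate = 0)
      tr <- run_cohort(spec)
      v <- spec$utilities
      occ <- as.matrix(tr[, spec$states])
      n <- spec$n_cycles
      start_counted <- sum(occ[1:n, ] %*% v)
      end_counted <- sum(occ[2:(n + 1), ] %*% v)
      corrected <- accumulate_value(tr, v, rate = 0, half_cycle = TRUE)
      expect_gte(corrected, min(start_counted, end_counted) - 1e-12)
      expect_lte(corrected, max(start_counted, end_counted) + 1e-12)
    }
  })
})

test_that("discount factors follow the first-cycle-undiscounted convention", {
  expect_equal(discount_factor(0, 1:10), rep(1, 10))
  expect_equal(discount_factor(0.05, 1), 1)
  expect_equal(discount_factor(0.05, 2), 1 / 1.05)
  expect_equal(discount_factor(0.05, 5), 1 / 1.05^4)
})

test_that("accumulate_value reduces to person-time and respects discounting", {
  s <- c("stable", "remission", "relapse", "death")
  m <- validate_transition_matrix(diag(4) |> `dimnames<-`(list(s, s)))
  ones <- setNames(c(1, 1, 1, 1), s)
  spec <- model_spec("static", m, utilities = ones - c(0, 0, 0, 1),
                     state_costs = ones, discount_rate = 0)
  tr <- run_cohort(spec)
  expect_equal(accumulate_value(tr, ones, rate = 0), 5) # 5 person-years
  expect_equal(accumulate_value(tr, ones * 0, rate = 0), 0)
  expect_lt(accumulate_value(tr, ones, rate = 0.05), 5) # discounting shrinks

  # rate 0 and half-cycle off: plain occupancy-weighted sum, 2-cycle hand case
  spec2 <- acth_spec(n_cycles = 2, discount_rate = 0, half_cycle = FALSE)
  tr2 <- run_cohort(spec2)
  v <- base_utilities()
  occ <- as.matrix(tr2[, spec2$states])
  expect_equal(accumulate_value(tr2, v), sum(occ[2:3, ] %*% v))

  expect_error(accumulate_value(tr2, c(stable = 1)),
               class = "markovcea_model_definition")
})

test_that("evaluate_strategy adds the one-off cost undiscounted at cycle 1", {
  out0 <- evaluate_strategy(acth_spec(intervention_cost = 0))
  out1 <- evaluate_strategy(acth_spec(intervention_cost = 3112))
  expect_equal(out1$cost - out0$cost, 3112)
  expect_equal(out1$effect, out0$effect)
  # trace table foots to the strategy totals
  tt <- trace_table(attr(out1, "trace"))
  expect_equal(sum(tt$cycle_cost), out1$cost)
  expect_equal(sum(tt$cycle_qaly), out1$effect)
})

test_that("model_spec rejects invalid definitions", {
  m <- acth_matrix()
  expect_error(model_spec("x", m, init = c(0.5, 0.2, 0.2, 0.2),
                          utilities = base_utilities(),
                          state_costs = base_utilities()),
               class = "markovcea_model_definition")
  expect_error(model_spec("x", m, utilities = c(stable = 2, remission = 1,
                                                relapse = 1, death = 0),
                          state_costs = base_utilities()),
               class = "markovcea_model_definition")
  expect_error(model_spec("x", m, utilities = base_utilities(),
                          state_costs = base_utilities(), discount_rate = -0.1),
               class = "markovcea_model_definition")
})
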