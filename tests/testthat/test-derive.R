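test_that("response and exit probability formulas match their closed forms", {
  expect_equal(prob_response(0.837), 1 - exp(-0.837 / 3))
  expect_equal(round(prob_response(0.837), 3), 0.243)
  expect_equal(round(prob_response(0.704), 3), 0.209)
  expect_lt(prob_response(1e-9), 1e-8) # rr -> 0+ limit

  expect_equal(prob_annual_exit(5.6), 1 - exp(-0.75 * log(2) / 5.6))
  expect_equal(round(prob_annual_exit(5.6), 3), 0.089)
  expect_equal(round(prob_annual_exit(44.3 - 7.2), 3), 0.014)
  expect_equal(prob_annual_exit(Inf), 0) # unbounded survival, no events

  expect_error(prob_response(-1), class = "markovcea_invalid_parameter")
  expect_error(prob_response(0), class = "markovcea_invalid_parameter")
  expect_error(prob_annual_exit(0), class = "markovcea_invalid_parameter")
  expect_error(prob_annual_exit(-3), class = "markovcea_invalid_parameter")
})

test_that("prob_annual_exit decreases and prob_response increases, both in (0,1)", {
  medians <- sort(runif(50, 0.5, 100))
  exits <- prob_annual_exit(medians)
  expect_true(all(diff(exits) < 0))
  expect_true(all(exits > 0 & exits < 1))

  rrs <- sort(runif(50, 0.01, 5))
  resp <- prob_response(rrs)
  expect_true(all(diff(resp) > 0))
  expect_true(all(resp > 0 & resp < 1))
})

test_that("derived row groups sum to exactly 1 in full-precision mode", {
  withr::with_seed(11, {
    for (i in 1:20) {
      s <- clinical_summary("X", rr = runif(1, 0.2, 2), os_median = runif(1, 30, 80),
                            ttp_median = runif(1, 3, 20), dor_median = runif(1, 4, 30))
      tab <- derive_transitions(s, rounding = "full")
      p <- setNames(tab$estimate, tab$param)
      expect_equal(p[["p_ss"]] + p[["p_sr"]] + p[["p_sp"]], 1, tolerance = 1e-15)
      expect_equal(p[["p_rr"]] + p[["p_rp"]], 1, tolerance = 1e-15)
      expect_equal(p[["p_pp"]] + p[["p_pd"]], 1, tolerance = 1e-15)
    }
  })
})

test_that("printed-precision chaining uses rounded intermediate values", {
  tab <- derive_transitions(tch_summary())
  p <- setNames(tab$estimate, tab$param)
  # p_rp printed at 2 dp, then chained: p_sp = 4 * 0.12, p_ss = 1 - 0.48 - 0.209
  expect_identical(p[["p_rp"]], 0.12)
  expect_identical(p[["p_sp"]], 0.48)
  expect_equal(p[["p_ss"]], 0.311)
  # full-precision mode does not reproduce the printed cells
  full <- derive_transitions(tch_summary(), rounding = "full")
  expect_false(isTRUE(all.equal(full$estimate[full$param == "p_rp"], 0.12,
                                tolerance = 1e-6)))
})

test_that("an infeasible stable row is rejected", {
  s <- clinical_summary("X", rr = 0.8, os_median = 44, ttp_median = 7,
                        dor_median = 0.5) # huge relapse exit -> p_sp > 1
  expect_error(derive_transitions(s), class = "markovcea_infeasible_matrix")
})

test_that("sa_range applies the fraction symmetrically and respects caps", {
  r <- sa_range(0.243, 0.2)
  expect_equal(c(r$lo, r$hi), c(0.1944, 0.2916))
  r <- sa_range(0.911, 0.2)
  expect_equal(c(r$lo, r$hi), c(0.7288, 1)) # cap at 1
  r <- sa_range(0, 0.2)
  expect_equal(c(r$lo, r$hi), c(0, 0))
  r <- sa_range(0.5, 0)
  expect_equal(c(r$lo, r$hi), c(0.5, 0.5)) # fraction 0 collapses the range
  r <- sa_range(100, 0.2, cap = c(0, Inf))
  expect_equal(c(r$lo, r$hi), c(80, 120))
})

test_that("transition_matrix builds a validated four-state chain", {
  m <- acth_matrix()
  expect_equal(rowSums(m), setNames(rep(1, 4), rownames(m)))
  expect_equal(unname(m["death", ]), c(0, 0, 0, 1))
  expect_equal(unname(m["stable", "death"]), 0) # death only from relapse
  expect_equal(unname(m["remission", "death"]), 0)

  expect_error(transition_matrix(c(p_ss = 0.5, p_sr = 0.5)),
               class = "markovcea_model_definition")
  bad <- unclass(m)
  bad[1, 1] <- bad[1, 1] + 0.01
  expect_error(validate_transition_matrix(bad),
               class = "markovcea_model_definition")
})

test_that("clinical_summary enforces its invariants", {
  expect_error(clinical_summary("X", rr = -1, os_median = 40, ttp_median = 7,
                                dor_median = 5),
               class = "markovcea_invalid_parameter")
  expect_error(clinical_summary("X", rr = 1, os_median = 7, ttp_median = 40,
                                dor_median = 5),
               class = "markovcea_invalid_parameter")
  expect_error(clinical_summary("X", rr = 1, os_median = 40, ttp_median = 7,
                                dor_median = 0),
               class = "markovcea_invalid_parameter")
})
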