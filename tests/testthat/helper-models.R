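# shared fixtures: built in code, no files

base_utilities <- function() {
  c(stable = 0.74, remission = 0.85, relapse = 0.5, death = 0)
}

acth_matrix <- function() transition_matrix(derive_transitions(acth_summary()))
tch_matrix <- function() transition_matrix(derive_transitions(tch_summary()))

acth_spec <- function(..., intervention_cost = 3112) {
  model_spec("ACTH", acth_matrix(), utilities = base_utilities(),
             state_costs = c(stable = 8942.12, remission = 3129.74,
                             relapse = 19672.66, death = 0),
             intervention_cost = intervention_cost, ...)
}

test_config <- function() default_config()

# random row-stochastic matrix over the four states with absorbing death
random_transition_matrix <- function() {
  s <- c("stable", "remission", "relapse", "death")
  m <- matrix(0, 4, 4, dimnames = list(from = s, to = s))
  for (i in 1:3) {
    w <- runif(4)
    m[i, ] <- w / sum(w)
  }
  m[4, ] <- c(0, 0, 0, 1)
  validate_transition_matrix(m)
}

# config with two identical arms (every arm-symmetric parameter has zero
# incremental swing)
symmetric_config <- function() {
  cfg <- default_config()
  cfg$arms[[2]] <- cfg$arms[[1]]
  cfg$arms[[2]]$label <- "MIRROR"
  cfg
}
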