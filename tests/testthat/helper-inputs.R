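# Shared fixtures, built in code.

# default inputs, loaded once per test file
ep_test_inputs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_config()
    cache
  }
})

# a degenerate variant: no transitions, no mortality, no discounting,
# whole cohort in one state; closed-form totals are then exact
ep_frozen_inputs <- function(state = "severe") {
  inputs <- load_config()
  eye <- diag(4)
  dimnames(eye) <- list(ep_states(alive_only = TRUE), ep_states(alive_only = TRUE))
  inputs$transitions$nht <- eye
  inputs$transitions$oc <- eye
  inputs$life_table$q_annual <- 0
  inputs$model$annual_discount_rate <- 0
  init <- stats::setNames(as.numeric(ep_states(alive_only = TRUE) == state),
                          ep_states(alive_only = TRUE))
  inputs$model$initial_distribution <- init
  inputs
}

# published table values used across tests
ep_table4 <- list(cost_nht = 1707, qaly_nht = 9.88,
                  cost_oc = 1113, qaly_oc = 10.31,
                  delta_cost = -594, delta_qaly = 0.43)
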