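# Cohort engine: matrix construction, discounting, closed-form accrual,
# conservation and the microsimulation cross-check.

test_that("mortality overlay builds the published rows at zero mortality", {
  inputs <- ep_test_inputs()
  M <- build_transition_matrix(inputs$transitions$nht, 0)
  expect_equal(unname(M["no_pain", ]), c(0.997, 0.003, 0, 0, 0))
  M2 <- build_transition_matrix(inputs$transitions$oc, 0)
  expect_equal(unname(M2["severe", ]), c(0, 0, 0.004, 0.996, 0))
  expect_equal(unname(M2["dead", ]), c(0, 0, 0, 0, 1))  # absorbing
})

test_that("mortality overlay scales alive rows and is total at q_annual = 1", {
  inputs <- ep_test_inputs()
  q <- 0.002
  M <- build_transition_matrix(inputs$transitions$nht, q)
  q_m <- 1 - (1 - q)^(1 / 12)
  expect_equal(unname(M[1:4, 5]), rep(q_m, 4))
  expect_equal(unname(rowSums(M)), rep(1, 5), tolerance = 1e-12)
  M1 <- build_transition_matrix(inputs$transitions$nht, 1)
  expect_equal(unname(M1[1:4, 5]), rep(1, 4))
  expect_error(build_transition_matrix(matrix(0.5, 4, 4), 0), "row-stochastic")
})

test_that("discount factors follow the compound monthly conversion", {
  expect_equal(discount_factor(0, 0.035), 1)
  expect_equal(discount_factor(12, 0.035), 1 / 1.035)
  expect_equal(discount_factor(24, 0.035), 1 / 1.035^2)
  expect_equal(discount_factor(0:10, 0), rep(1, 11))
  expect_error(discount_factor(5, -0.01), ">= 0")
  # simple mode compounds a flat monthly rate
  expect_equal(discount_factor(12, 0.035, "simple"), (1 + 0.035 / 12)^-12)
})

test_that("frozen cohort reproduces closed-form totals", {
  # no transitions, no deaths, no discounting: totals are exact products
  sev <- run_cohort(ep_frozen_inputs("severe"), "nht")
  expect_equal(sev$result$qaly, 18 * 0.573)            # 10.314
  expect_equal(sev$result$cost, 216 * (26.67 / 3 + 2.31 + 2.43))
  nop <- run_cohort(ep_frozen_inputs("no_pain"), "nht")
  expect_equal(nop$result$qaly, 18 * 0.905)
  expect_equal(nop$result$cost, 18 * 12 * 26.67 / 3)   # GP cost only: 1920.24
  # OC arm adds the amortised pack cost in every state
  oc <- run_cohort(ep_frozen_inputs("no_pain"), "oc")
  expect_equal(oc$result$cost, 18 * 12 * (26.67 / 6 + 2.82 / 3))
})

test_that("trace conserves occupancy and the dead state is monotone", {
  run <- run_cohort(ep_test_inputs(), "nht")
  occ <- run$occupancy
  expect_equal(unname(rowSums(occ)), rep(1, nrow(occ)), tolerance = 1e-9)
  expect_true(all(diff(occ[, "dead"]) >= -1e-15))
  expect_true(all(occ >= -1e-15))
})

test_that("discounting and half-cycle correction bound the totals correctly", {
  inputs <- ep_test_inputs()
  for (arm in ep_arms()) {
    run <- run_cohort(inputs, arm)
    expect_lt(run$result$cost, run$result$cost_undiscounted)
    expect_lt(run$result$qaly, run$result$qaly_undiscounted)
    # trapezoid lies between start-of-cycle and end-of-cycle conventions
    start_conv <- run_cohort(inputs, arm, half_cycle_correction = FALSE)$result
    occ <- run$occupancy
    T_ <- inputs$model$n_cycles
    df <- discount_factor(0:(T_ - 1), inputs$model$annual_discount_rate)
    u <- run$pars$utilities
    end_qaly <- sum(df * (occ[2:(T_ + 1), 1:4] %*% (u / 12)))
    hcc_qaly <- run$result$qaly
    expect_true(hcc_qaly <= max(start_conv$qaly, end_qaly) + 1e-12)
    expect_true(hcc_qaly >= min(start_conv$qaly, end_qaly) - 1e-12)
  }
})

test_that("totals respond monotonically to utilities and the discount rate", {
  inputs <- ep_test_inputs()
  base <- run_cohort(inputs, "nht")$result
  up <- arm_parameters(inputs, "nht",
                       utilities = c(no_pain = 0.905, mild = 0.81,
                                     moderate = 0.718, severe = 0.573))
  expect_gt(run_cohort(inputs, pars = up)$result$qaly, base$qaly)
  hi <- inputs; hi$model$annual_discount_rate <- 0.06
  richer <- run_cohort(hi, "nht")$result
  expect_lt(richer$qaly, base$qaly)
  expect_lt(richer$cost, base$cost)
})

test_that("alive mass decays exactly with survival when transitions conserve it", {
  inputs <- ep_frozen_inputs("moderate")
  inputs$life_table$q_annual <- 0.01
  run <- run_cohort(inputs, "nht")
  occ <- run$occupancy
  q_m <- 1 - (1 - 0.01)^(1 / 12)
  t_check <- c(1, 12, 100, 216)
  expect_equal(rowSums(occ[t_check + 1, 1:4, drop = FALSE]),
               (1 - q_m)^t_check, tolerance = 1e-12)
})

test_that("lumped GP billing is a small perturbation of the amortised default", {
  inputs <- ep_test_inputs()
  lumped <- inputs; lumped$costs$gp_cost_mode <- "lumped"
  for (arm in ep_arms()) {
    a <- run_cohort(inputs, arm)$result$cost
    l <- run_cohort(lumped, arm)$result$cost
    expect_lt(abs(a - l) / a, 0.005)
    expect_false(isTRUE(all.equal(a, l)))  # the flag does change the accounting
  }
})

test_that("trace CSV export has the documented long layout", {
  run <- run_cohort(ep_test_inputs(), "oc")
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(run, path)
  tr <- read.csv(path)
  expect_equal(names(tr), c("cycle", "age", "state", "occupancy",
                            "effective_occupancy", "discount_factor",
                            "cost_accrued", "qaly_accrued"))
  expect_equal(nrow(tr), 216 * 5)
  by_cycle <- as.numeric(tapply(tr$occupancy, tr$cycle, sum))
  expect_equal(by_cycle, rep(1, 216), tolerance = 1e-9)
})

test_that("microsimulation is exact when the path has no randomness", {
  inputs <- ep_frozen_inputs("severe")
  ms <- run_microsim(inputs, "nht", n_patients = 50, seed = 9)
  expect_equal(ms$qaly, 18 * 0.573)
  expect_equal(ms$qaly_se, 0)
  expect_equal(ms$cost, 216 * (26.67 / 3 + 2.31 + 2.43))
})

test_that("microsimulation re-runs are bit-identical under a fixed seed", {
  inputs <- ep_test_inputs()
  a <- run_microsim(inputs, "oc", n_patients = 500, seed = 21)
  b <- run_microsim(inputs, "oc", n_patients = 500, seed = 21)
  expect_identical(a, b)
})

test_that("cohort totals agree with the microsimulation oracle (moderate n)", {
  inputs <- ep_test_inputs()
  cohort <- run_cohort(inputs, "nht")$result
  ms <- run_microsim(inputs, "nht", n_patients = 20000, seed = 4)
  expect_lt(abs(cohort$qaly - ms$qaly), 3 * ms$qaly_se)
  expect_lt(abs(cohort$cost - ms$cost), 3 * ms$cost_se)
})
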