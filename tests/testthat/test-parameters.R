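# Configuration loading: the bundled default must reproduce every published
# parameter; invariants must be enforced with errors naming the field.

test_that("state space and NRS ranges partition the 0-10 pain scale", {
  nrs <- ep_nrs_ranges()
  expect_equal(nrs$state, c("no_pain", "mild", "moderate", "severe"))
  covered <- unlist(Map(seq, nrs$nrs_low, nrs$nrs_high))
  expect_equal(sort(covered), 0:10)           # cover, no overlap
  expect_equal(nrs$nrs_low[1], 0)             # no pain is NRS 0 exactly
  expect_equal(nrs$nrs_high[1], 0)
})

test_that("bundled default configuration reproduces the published cost inputs", {
  cc <- ep_test_inputs()$costs
  expect_equal(cc$gp_visit_cost, 26.67)
  expect_equal(cc$gp_interval_months$nht, 3)
  expect_equal(cc$gp_interval_months$oc, 6)
  expect_equal(cc$oc_pack_cost, 2.82)
  expect_equal(cc$paracetamol_month_max, 2.31)
  expect_equal(cc$ibuprofen_month_max, 2.43)
  # dose-scaling rule: none / half paracetamol / full / full + ibuprofen
  pars <- arm_parameters(ep_test_inputs(), "nht")
  expect_equal(unname(pars$analgesic),
               c(0, 0.5 * 2.31, 2.31, 2.31 + 2.43))
})

test_that("bundled default configuration reproduces the published utilities", {
  uu <- ep_test_inputs()$utilities
  expect_equal(vapply(uu, `[[`, numeric(1), "mean"),
               c(no_pain = 0.905, mild = 0.802, moderate = 0.718, severe = 0.573))
  expect_equal(uu$no_pain$alpha, 27.357)
  expect_equal(uu$no_pain$beta, 3.153)
  expect_equal(uu$mild$alpha, 82.023)
  expect_equal(uu$mild$beta, 18.242)
  expect_equal(uu$moderate$alpha, 55.931)
  expect_equal(uu$moderate$beta, 22.142)
  expect_equal(uu$severe$alpha, 19.336)
  expect_equal(uu$severe$beta, 14.487)
})

test_that("bundled default configuration reproduces the published transition table", {
  tr <- ep_test_inputs()$transitions
  nht <- tr$nht; oc <- tr$oc
  expect_equal(nht["no_pain", "mild"], 0.003)
  expect_equal(nht["mild", "no_pain"], 0.002)
  expect_equal(nht["mild", "moderate"], 0.002)
  expect_equal(nht["moderate", "mild"], 0.001)
  expect_equal(nht["moderate", "severe"], 0.003)
  expect_equal(nht["severe", "moderate"], 0.0001)
  expect_equal(oc["no_pain", "mild"], 0.001)
  expect_equal(oc["mild", "no_pain"], 0.003)
  expect_equal(oc["mild", "moderate"], 0.0015)
  expect_equal(oc["moderate", "mild"], 0.003)
  expect_equal(oc["moderate", "severe"], 0.0001)
  expect_equal(oc["severe", "moderate"], 0.004)
  # rows are stochastic and only adjacent severities move
  for (P in list(nht, oc)) {
    expect_equal(unname(rowSums(P)), rep(1, 4))
    expect_equal(P["no_pain", "moderate"], 0)
    expect_equal(P["no_pain", "severe"], 0)
    expect_equal(P["mild", "severe"], 0)
    expect_equal(P["severe", "no_pain"], 0)
  }
  # PSA pseudo-counts as published
  expect_equal(tr$nht_psa$severe$moderate$alpha, 0.1)
  expect_equal(tr$nht_psa$severe$moderate$beta, 999.9)
  expect_equal(tr$oc_psa$mild$moderate$alpha, 1.5)
  expect_equal(tr$oc_psa$mild$moderate$beta, 998.5)
})

test_that("model settings match the published design", {
  m <- ep_test_inputs()$model
  expect_equal(m$start_age, 32)
  expect_equal(m$end_age, 50)
  expect_equal(m$n_cycles, 216L)
  expect_equal(m$annual_discount_rate, 0.035)
  expect_true(m$half_cycle_correction)
  expect_equal(sum(m$initial_distribution), 1)
})

test_that("configuration round-trips through serialisation unchanged", {
  inputs <- ep_test_inputs()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(inputs, path)
  back <- load_config(path)
  expect_equal(back$transitions$nht, inputs$transitions$nht)
  expect_equal(back$transitions$oc, inputs$transitions$oc)
  expect_equal(back$utilities, inputs$utilities)
  expect_equal(back$model$initial_distribution, inputs$model$initial_distribution)
  expect_equal(back$costs$analgesic_scaling, inputs$costs$analgesic_scaling)
  expect_equal(back$life_table, inputs$life_table)
})

test_that("invariant violations are rejected with the field named", {
  base <- yaml::read_yaml(ep_default_config())
  reload <- function(cfg) {
    p <- withr::local_tempfile(fileext = ".yaml", .local_envir = parent.frame(2))
    yaml::write_yaml(cfg, p)
    load_config(p)
  }
  bad <- base; bad$model$initial_distribution$no_pain <- 0.0
  bad$model$initial_distribution$mild <- 0.4
  bad$model$initial_distribution$moderate <- 0.4
  bad$model$initial_distribution$severe <- 0.1
  expect_error(reload(bad), "initial_distribution must sum to 1")

  bad <- base; bad$utilities$mild$mean <- 0.95  # above no-pain
  expect_error(reload(bad), "strictly decrease")

  bad <- base; bad$transitions$nht$no_pain$severe <- list(p = 0.001, alpha = 1, beta = 999)
  expect_error(reload(bad), "adjacent")

  bad <- base; bad$costs$gp_visit_cost <- -5
  expect_error(reload(bad), "costs must be >= 0")

  bad <- base; bad$model$end_age <- 30
  expect_error(reload(bad), "end_age")

  bad <- base; bad$transitions$nht$no_pain$mild$p <- 1.2
  expect_error(reload(bad), "probability")
})

test_that("missing files and parse failures give informative errors", {
  expect_error(load_config("/nonexistent/conf.yaml"), "not found")
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines("model: [unclosed", p)
  expect_error(load_config(p), "parse failure")
})

test_that("life-table coverage of the modelled ages is enforced", {
  lt <- make_life_table(ages = 32:40)   # stops short of end_age
  expect_error(validate_life_table(lt, 32, 50), "cover ages")
  expect_silent(validate_life_table(make_life_table(), 32, 50))
  bad <- make_life_table(); bad$q_annual[3] <- 1.2
  expect_error(validate_life_table(bad), "in \\[0, 1\\)")
})

test_that("bundled life-table file equals the generator defaults", {
  bundled <- read.csv(system.file("extdata", "life_table_synthetic.csv",
                                  package = "endopain"))
  expect_equal(bundled, make_life_table(), tolerance = 1e-12)
})
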