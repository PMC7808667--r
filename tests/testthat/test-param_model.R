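test_that("annual/cycle probability conversions match closed forms and round-trip", {
  expect_equal(annual_to_cycle_prob(0, 4), 0)
  expect_equal(annual_to_cycle_prob(1, 4), 1)
  expect_equal(annual_to_cycle_prob(0.25, 4), 1 - 0.75^(1 / 4), tolerance = 1e-12)
  expect_equal(annual_to_cycle_prob(0.25, 4), 0.069395, tolerance = 1e-5)

  expect_equal(cycle_to_annual_prob(0.069395, 4), 0.25, tolerance = 1e-4)
  expect_equal(cycle_to_annual_prob(0.10210, 4), 0.35, tolerance = 1e-3)
  expect_equal(cycle_to_annual_prob(0, 4), 0)

  # identity on a grid, machine precision
  p <- seq(0, 1, by = 0.01)
  expect_equal(cycle_to_annual_prob(annual_to_cycle_prob(p, 4), 4), p,
               tolerance = 1e-12)
  expect_equal(cycle_to_annual_prob(annual_to_cycle_prob(p, 12), 12), p,
               tolerance = 1e-12)
  # the reverse direction holds wherever (1 - p)^k stays representable
  q <- seq(0, 0.9, by = 0.01)
  expect_equal(annual_to_cycle_prob(cycle_to_annual_prob(q, 4), 4), q,
               tolerance = 1e-12)
})

test_that("probability conversion is monotone in rate and in cycle count", {
  p <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(annual_to_cycle_prob(p, 4)) > 0))
  for (pp in c(0.1, 0.5, 0.9)) {
    by_cycles <- vapply(1:12, function(k) annual_to_cycle_prob(pp, k), numeric(1))
    expect_true(all(diff(by_cycles) < 0))
  }
})

test_that("out-of-range probabilities are rejected with the offending value named", {
  expect_error(annual_to_cycle_prob(1.2, 4), "p_annual.*1\\.2")
  expect_error(annual_to_cycle_prob(-0.1, 4), "p_annual")
  expect_error(cycle_to_annual_prob(2, 4), "p_cycle")
  expect_error(annual_to_cycle_prob(0.5, 0), "cycles_per_year")
})

test_that("scenario specs encode the device/care-package combinations", {
  expect_false(scenario_spec("SC")$device_active)
  expect_identical(scenario_spec("SC")$care_package, "standard")
  expect_true(scenario_spec("S0")$device_active)
  expect_identical(scenario_spec("S0")$care_package, "nominal")
  expect_identical(scenario_spec("S1")$care_package, "none")
  expect_identical(scenario_spec("S2")$care_package, "standard")
  expect_error(scenario_spec("S9"))
})

test_that("dose regimens activate the right cycles", {
  expect_identical(dose_regimen("single_annual", 20)$active_cycles,
                   c(0L, 4L, 8L, 12L, 16L))
  expect_identical(dose_regimen("continuous", 4)$active_cycles, 0:3)
  expect_length(dose_regimen("single_annual", 0)$active_cycles, 0)
})

test_that("loading a minimal config applies published costs and cohort defaults", {
  ps <- load_parameter_set(minimal_config_yaml())
  expect_s3_class(ps, "parameter_set")
  expect_equal(ps$state_costs[["Progressive"]], 828.43)
  expect_equal(ps$cohort_size, 1000)
  expect_equal(ps$cycle_length, 0.25)
  expect_equal(ps$device_rental_rate, 15)
  # annual-suffixed entries pass through the rate conversion
  M <- ps$transitions$sc$base_matrix
  expect_equal(M["Severe", "Dead"], annual_to_cycle_prob(0.25, 4))
  # device arm derived by scaling progression
  expect_lt(ps$transitions$flowox$base_matrix["Progressive", "Severe"],
            M["Progressive", "Severe"])
})

test_that("config errors name the offending key or rule", {
  expect_error(load_parameter_set("costs: {Mild: 10}"), "transitions")
  bad_cost <- paste0(minimal_config_yaml(), "\ncosts: {Severe: -5}\n")
  expect_error(load_parameter_set(bad_cost), "negative care cost.*Severe")
  bad_state <- sub("Progressive:", "Banana:", minimal_config_yaml())
  expect_error(load_parameter_set(bad_state), "unknown state.*Banana")
})

test_that("serialise then reload reproduces the parameter set", {
  ps <- base_ps(seed = 7)
  path <- withr::local_tempfile(fileext = ".yaml")
  serialise_parameter_set(ps, path)
  ps2 <- load_parameter_set(path)
  expect_equal(ps2$state_costs, ps$state_costs)
  expect_equal(ps2$utilities, ps$utilities, tolerance = 1e-12)
  expect_equal(ps2$transitions$sc$base_matrix, ps$transitions$sc$base_matrix,
               tolerance = 1e-12)
  expect_equal(ps2$transitions$flowox$base_matrix,
               ps$transitions$flowox$base_matrix, tolerance = 1e-12)
  expect_equal(ps2$discount_rate_cost, ps$discount_rate_cost)
  expect_equal(ps2$cohort_size, ps$cohort_size)
  # and the round trip is stable under a second pass
  expect_identical(serialise_parameter_set(ps2), serialise_parameter_set(ps2))
})

test_that("validation reports ordering and absorbing-state violations without raising", {
  ps <- base_ps()
  expect_length(validate_parameter_set(ps), 0)

  bad_u <- ps
  bad_u$utilities["Severe"] <- bad_u$utilities["Progressive"] + 0.1
  report <- validate_parameter_set(bad_u)
  expect_length(report, 1)
  expect_match(report, "utilities must decrease")

  dead_u <- ps
  dead_u$utilities["Dead"] <- 0.1
  expect_match(validate_parameter_set(dead_u), "absorbing state", all = FALSE)

  # the input is never mutated
  expect_length(validate_parameter_set(ps), 0)
})

test_that("reported labels aggregate the recovered sub-states", {
  expect_identical(reported_label("RecoveredNoAmp"), "Recovered")
  expect_identical(reported_label("RecoveredPostAmp"), "Recovered")
  expect_identical(reported_label("Dead"), "Dead")
  expect_error(reported_label("Limbo"), "unknown health state")
})
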