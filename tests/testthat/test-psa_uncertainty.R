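# A tiny hand-built psa_result for summary-level tests.
fake_psa <- function(delta_cost, delta_qalys, scenario = "S0") {
  structure(list(
    draws = data.frame(draw = seq_along(delta_cost),
                       scenario = rep_len(scenario, length(delta_cost)),
                       delta_cost = delta_cost, delta_qalys = delta_qalys),
    scenarios = unique(scenario)), class = "psa_result")
}

test_that("degenerate distributions return the base case exactly", {
  ps <- base_ps()
  spec <- psa_spec(n_draws = 1, cost_cv = 0, prob_ess = Inf, utility_ess = Inf)
  set.seed(1)
  drawn <- draw_parameters(ps, spec)
  expect_equal(drawn$state_costs, ps$state_costs)
  expect_equal(drawn$utilities, ps$utilities)
  expect_equal(drawn$transitions$sc$base_matrix, ps$transitions$sc$base_matrix)
})

test_that("draws are reproducible given the seed and respect supports", {
  ps <- base_ps()
  spec <- psa_spec(n_draws = 1, seed = 11)
  set.seed(11); a <- draw_parameters(ps, spec)
  set.seed(11); b <- draw_parameters(ps, spec)
  expect_identical(a, b)

  set.seed(99)
  for (i in 1:5) {
    d <- draw_parameters(ps, spec)
    expect_length(validate_parameter_set(d), 0)
    expect_true(all(d$utilities >= spec$utility_lower & d$utilities <= 1))
    expect_true(all(d$state_costs >= 0))
    M <- d$transitions$sc$base_matrix
    expect_equal(unname(rowSums(M)), rep(1, 8), tolerance = 1e-9)
  }
})

test_that("cost draws are centred on the base case (gamma mean)", {
  ps <- base_ps()
  spec <- psa_spec(cost_cv = 0.2, prob_ess = Inf, utility_ess = Inf)
  set.seed(5)
  draws <- replicate(1000, draw_parameters(ps, spec)$state_costs[["Progressive"]])
  se <- 828.43 * 0.2 / sqrt(1000)
  expect_lt(abs(mean(draws) - 828.43), 3 * se)
})

test_that("a zero-dispersion single-draw PSA collapses to the deterministic result", {
  ps <- base_ps(horizon_cycles = 4L)
  spec <- psa_spec(n_draws = 1, cost_cv = 0, prob_ess = Inf, utility_ess = Inf,
                   seed = 3)
  psa <- run_psa(ps, spec, scenarios = "S0", horizon_cycles = 4)
  det <- incremental(evaluate_scenario(ps, "S0", horizon_cycles = 4),
                     evaluate_scenario(ps, "SC", horizon_cycles = 4))
  expect_equal(psa$draws$delta_cost, det$delta_cost, tolerance = 1e-12)
  expect_equal(psa$draws$delta_qalys, det$delta_qalys, tolerance = 1e-12)
})

test_that("identical seeds reproduce the PSA result exactly", {
  ps <- base_ps(horizon_cycles = 4L)
  spec <- psa_spec(n_draws = 20, seed = 42)
  a <- run_psa(ps, spec, horizon_cycles = 4)
  b <- run_psa(ps, spec, horizon_cycles = 4)
  expect_identical(a$draws, b$draws)
  spec2 <- psa_spec(n_draws = 20, seed = 43)
  c <- run_psa(ps, spec2, horizon_cycles = 4)
  expect_false(identical(a$draws$delta_cost, c$draws$delta_cost))
})

test_that("CEAC probabilities hit their limits and the constructed mixture", {
  psa <- fake_psa(delta_cost = c(rep(-10, 5), rep(10, 5)),
                  delta_qalys = rep(0.1, 10))
  kurve <- ceac(psa, lambdas = c(0, 1e9))
  expect_equal(kurve$probability[kurve$lambda == 0], 0.5)
  expect_equal(kurve$probability[kurve$lambda == 1e9], 1.0)

  # all dearer: probability 0 at lambda = 0
  psa2 <- fake_psa(delta_cost = rep(10, 6), delta_qalys = rep(0.1, 6))
  expect_equal(ceac(psa2, lambdas = 0)$probability, 0)

  # half dominant, half with ICER above lambda -> 0.5
  psa3 <- fake_psa(delta_cost = c(rep(-5, 10), rep(100, 10)),
                   delta_qalys = rep(0.01, 20))
  expect_equal(ceac(psa3, lambdas = 5000)$probability, 0.5)

  expect_error(ceac(fake_psa(numeric(0), numeric(0))), "no PSA draws")
})

test_that("CEAC is non-decreasing in lambda when every draw gains QALYs", {
  set.seed(7)
  psa <- fake_psa(delta_cost = rnorm(200, 500, 800),
                  delta_qalys = runif(200, 0.01, 0.3))
  kurve <- ceac(psa, lambdas = seq(0, 60000, by = 1000))
  expect_true(all(diff(kurve$probability) >= 0))
  # limits: P(delta_e > 0) at infinity, P(delta_c < 0) at zero
  expect_equal(kurve$probability[1], mean(psa$draws$delta_cost < 0))
  expect_equal(ceac(psa, lambdas = 1e12)$probability,
               mean(psa$draws$delta_qalys > 0))
})

test_that("bootstrap CEAC intervals behave like binomial intervals", {
  psa_all <- fake_psa(delta_cost = rep(-1, 50), delta_qalys = rep(0.1, 50))
  ci <- ceac_ci(psa_all, lambda = 0, n_boot = 200)
  expect_equal(as.vector(ci), c(1, 1))

  psa_none <- fake_psa(delta_cost = rep(1, 50), delta_qalys = rep(-0.1, 50))
  ci0 <- ceac_ci(psa_none, lambda = 0, n_boot = 200)
  expect_equal(as.vector(ci0), c(0, 0))

  # Bernoulli(0.8) acceptance at n = 1000: width ~ 2 * 1.96 * sqrt(.8*.2/1000)
  set.seed(21)
  acc <- rbinom(1000, 1, 0.8)
  psa_b <- fake_psa(delta_cost = ifelse(acc == 1, -1, 1),
                    delta_qalys = rep(0, 1000))
  ci_b <- ceac_ci(psa_b, lambda = 0, n_boot = 500)
  expect_gt(ci_b[["upper"]], 0.8 - 0.05)
  expect_lt(ci_b[["lower"]], 0.8 + 0.05)
  width <- ci_b[["upper"]] - ci_b[["lower"]]
  expect_equal(width, 2 * 1.96 * sqrt(0.8 * 0.2 / 1000), tolerance = 0.3)
  expect_error(ceac_ci(psa_b, lambda = 0, n_boot = 10), "n_boot")
})

test_that("CE-plane quadrants follow the sign convention", {
  psa <- fake_psa(delta_cost = c(-1, 1, 1, -1, 0),
                  delta_qalys = c(0.1, 0.1, -0.1, -0.1, 0))
  pts <- ce_plane(psa)
  expect_identical(pts$quadrant, c("SE", "NE", "NW", "SW", "origin"))
  expect_identical(pts$flagged, c(FALSE, FALSE, FALSE, FALSE, TRUE))
})

test_that("net-benefit intervals cover the mean and narrow with certainty", {
  psa <- fake_psa(delta_cost = rep(-100, 10), delta_qalys = rep(0.1, 10))
  tab <- imnb_ci(psa, lambdas = c(0, 20000))
  expect_equal(tab$mean_imnb, c(100, 2100))
  expect_equal(tab$lower, tab$upper)  # degenerate draws, degenerate interval
})
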