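test_that("validate_matrix reports row sums, bounds, absorption and structure", {
  expect_length(validate_matrix(identity_matrix_8()), 0)

  M <- identity_matrix_8()
  M["Severe", "Severe"] <- 0.98
  expect_match(validate_matrix(M), "row Severe sums to 0.98", all = FALSE)

  M <- identity_matrix_8()
  M["Dead", "Mild"] <- 0.1
  M["Dead", "Dead"] <- 0.9
  expect_match(validate_matrix(M), "Dead must be absorbing", all = FALSE)

  M <- identity_matrix_8()
  M["Progressive", "RecoveredPostAmp"] <- 0.1
  M["Progressive", "Progressive"] <- 0.9
  expect_match(validate_matrix(M), "RecoveredPostAmp may only be entered",
               all = FALSE)

  M <- identity_matrix_8()
  M["MajorAmputation", "RecoveredNoAmp"] <- 0.1
  M["MajorAmputation", "MajorAmputation"] <- 0.9
  expect_match(validate_matrix(M), "cannot transition to RecoveredNoAmp",
               all = FALSE)
})

test_that("transition sequences apply time-varying post-amputation mortality", {
  ps <- base_ps()
  mats <- build_transition_sequence(ps, "SC", 8)
  expect_length(mats, 8)
  p_y1 <- annual_to_cycle_prob(0.35, 4)
  p_later <- annual_to_cycle_prob(0.19, 4)
  for (t in 1:4) {
    expect_equal(mats[[t]]["MajorAmputation", "Dead"], p_y1, tolerance = 1e-12)
  }
  for (t in 5:8) {
    expect_equal(mats[[t]]["MajorAmputation", "Dead"], p_later, tolerance = 1e-12)
  }
  # without rules all matrices are identical copies of the base
  tm <- transition_model(ps$transitions$sc$base_matrix)
  ps2 <- ps
  ps2$transitions$sc <- tm
  mats2 <- build_transition_sequence(ps2, "SC", 3)
  expect_identical(mats2[[1]], mats2[[3]])
  expect_length(build_transition_sequence(ps, "SC", 0), 0)
})

test_that("a rule referencing an unknown state is a configuration error", {
  ps <- base_ps()
  expect_error(
    transition_model(ps$transitions$sc$base_matrix,
                     time_varying = list(list(state = "Limbo", cycles = 0:3,
                                              row = c(Dead = 1)))),
    "unknown state")
})

test_that("cohort propagation reproduces the one-year mortality anchors", {
  # 25%/year anchor on the per-cycle scale
  p <- annual_to_cycle_prob(0.25, 4)
  tr <- run_cohort(rep(list(two_state_matrix(p)), 4), c(Alive = 1000, Dead = 0))
  expect_equal(unname(tr$occupancy["cycle4", "Dead"]), 250, tolerance = 0.1 / 250)

  # 35%/year post-amputation anchor as a cumulative percentage
  p35 <- annual_to_cycle_prob(0.35, 4)
  tr35 <- run_cohort(rep(list(two_state_matrix(p35)), 4), c(Alive = 1000, Dead = 0))
  pct_dead <- 100 * tr35$occupancy["cycle4", "Dead"] / 1000
  expect_equal(unname(pct_dead), 35, tolerance = 0.1 / 35)

  # identity transitions leave the trace constant
  tr_id <- run_cohort(rep(list(identity_matrix_8()), 4), "Progressive",
                      cohort_size = 500)
  expect_true(all(tr_id$occupancy[, "Progressive"] == 500))
})

test_that("traces conserve the cohort and death is monotone", {
  for (seed in 1:5) {
    ps <- base_ps(seed = seed)
    for (sid in c("SC", "S0")) {
      mats <- build_transition_sequence(ps, sid, 20)
      tr <- run_cohort(mats, ps$initial_state, cohort_size = ps$cohort_size)
      expect_equal(unname(rowSums(tr$occupancy)), rep(1000, 21),
                   tolerance = 1e-9)
      expect_true(all(diff(tr$occupancy[, "Dead"]) >= -1e-12))
    }
  }
})

test_that("with everywhere-positive death probability the cohort is absorbed", {
  ps <- base_ps()
  mats <- build_transition_sequence(ps, "SC", 1200)
  tr <- run_cohort(mats, "Progressive", cohort_size = 1000)
  expect_gt(unname(tr$occupancy["cycle1200", "Dead"]), 999)
})

test_that("relabelling states permutes the trace columns identically", {
  ps <- base_ps(seed = 3)
  mats <- build_transition_sequence(ps, "SC", 8)
  init <- setNames(numeric(8), pad_states())
  init["Progressive"] <- 1000
  tr <- run_cohort(mats, init)

  perm <- c(3, 1, 2, 5, 4, 7, 8, 6)
  mats_p <- lapply(mats, function(M) M[perm, perm])
  tr_p <- run_cohort(mats_p, init[perm])
  expect_equal(tr_p$occupancy, tr$occupancy[, perm])
})

test_that("aggregation to reported states sums recovery and conserves the cohort", {
  occ <- matrix(0, 2, 8, dimnames = list(c("cycle0", "cycle1"), pad_states()))
  occ[1, "Progressive"] <- 1000
  occ[2, ] <- c(0, 950, 10, 0, 0, 10, 10, 20)
  tr <- structure(list(occupancy = occ, cohort_size = 1000,
                       cycle_length = 0.25, n_cycles = 1L),
                  class = "cohort_trace")
  agg <- aggregate_trace(tr)
  expect_identical(colnames(agg$occupancy), pad_reported_states())
  expect_equal(unname(agg$occupancy["cycle1", "Recovered"]), 20)
  expect_equal(unname(rowSums(agg$occupancy)), c(1000, 1000))

  # empty recovery column: identical values on the shared columns
  occ[2, ] <- c(0, 970, 10, 0, 0, 0, 0, 20)
  tr$occupancy <- occ
  agg2 <- aggregate_trace(tr)
  expect_equal(unname(agg2$occupancy[, "Recovered"]), c(0, 0))
  expect_equal(agg2$occupancy[, "Progressive"], occ[, "Progressive"])
})

test_that("trace export carries cycle index and calendar time", {
  p <- annual_to_cycle_prob(0.25, 4)
  tr <- run_cohort(rep(list(two_state_matrix(p)), 4), c(Alive = 1000, Dead = 0))
  df <- as.data.frame(tr)
  expect_identical(df$cycle, 0:4)
  expect_equal(df$years, seq(0, 1, by = 0.25))
})
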