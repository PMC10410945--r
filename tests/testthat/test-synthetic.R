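test_that("generated scenarios are valid by construction and reproducible", {
  b <- scenario_blueprint(n_states = 4, seed = 99)
  s1 <- generate_scenario(b)
  s2 <- generate_scenario(b)
  expect_equal(unclass(s1$matrix), unclass(s2$matrix))
  expect_identical(s1$utilities, s2$utilities)
  expect_identical(s1$comparator, s2$comparator)
  expect_no_error(validate_transition_matrix(s1$matrix))
  expect_error(scenario_blueprint(n_states = 1), "at least 2")
})

test_that("progression ordering yields monotone rewards", {
  scn <- generate_scenario(scenario_blueprint(n_states = 6, seed = 3,
                                              progression_ordering = TRUE))
  live <- setdiff(states(scn$matrix), "death")
  expect_false(is.unsorted(rev(scn$utilities[live])))
  expect_false(is.unsorted(scn$reference$cost[live][-1]))
})

test_that("a sweep of random scenarios always validates", {
  for (scn in random_scenarios(60)) {
    expect_no_error(validate_transition_matrix(scn$matrix))
    expect_no_error(build_strategies(scn))
    expect_true(scn$comparator$relative_risk > 0 &&
                  scn$comparator$relative_risk <= 1)
  }
})

test_that("microsimulation equals cohort evaluation exactly on a deterministic chain", {
  p <- rbind(stage_1 = c(stage_1 = 0, stage_2 = 1, death = 0),
             stage_2 = c(stage_1 = 0, stage_2 = 0, death = 1),
             death   = c(stage_1 = 0, stage_2 = 0, death = 1))
  scn <- cea_scenario(
    name = "deterministic-chain",
    matrix = transition_matrix(p),
    utilities = c(stage_1 = 0.9, stage_2 = 0.4, death = 0),
    reference = list(name = "SoC",
                     cost = c(stage_1 = 100, stage_2 = 500, death = 0)),
    comparator = list(name = "DMT",
                      cost = c(stage_1 = 1000, stage_2 = 500, death = 0),
                      relative_risk = 1, source_state = "stage_1"),
    conventions = list(reward_timing = "begin", apply_discount = TRUE),
    discount = list(rate = 0.05, first_cycle_undiscounted = TRUE),
    threshold = 30000, horizon = 4, cohort_size = 10
  )
  ev <- evaluate_scenario(scn)$reference
  ms <- microsimulate(scn, "reference", n_individuals = 37, seed = 1)
  expect_equal(ms$cost, ev$total_cost, tolerance = 1e-12)
  expect_equal(ms$qaly, ev$total_qaly, tolerance = 1e-12)
  expect_equal(ms$cost_se, 0)
})

test_that("microsimulation agrees with the cohort engine within 3 SE", {
  for (i in 1:2) {
    scn <- generate_scenario(scenario_blueprint(n_states = 3 + i, seed = 40 + i))
    arm <- if (i == 1) "reference" else "comparator"
    ev <- evaluate_scenario(scn)[[arm]]
    ms <- microsimulate(scn, arm, n_individuals = 50000, seed = 7)
    expect_lt(abs(ms$cost - ev$total_cost), 3 * ms$cost_se)
    expect_lt(abs(ms$qaly - ev$total_qaly), 3 * ms$qaly_se)
  }
})

test_that("a single simulated path is valid and bounded", {
  scn <- generate_scenario(scenario_blueprint(seed = 12))
  ms <- microsimulate(scn, "reference", n_individuals = 1, seed = 3)
  expect_true(is.finite(ms$cost) && ms$cost >= 0)
  expect_true(ms$qaly >= 0 && ms$qaly <= scn$horizon)
})
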