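test_that("the shipped Alzheimer scenario carries the published parameters", {
  scn <- alzheimer_scenario()
  expect_equal(scn$threshold, 28617)
  expect_equal(scn$horizon, 5)
  expect_equal(scn$cohort_size, 1000)
  expect_equal(scn$discount$rate, 0.06)
  expect_identical(states(scn$matrix), c("mild", "moderate", "severe", "death"))
  expect_identical(absorbing_states(scn$matrix), "death")
  expect_equal(unname(scn$matrix["mild", ]), c(0.774, 0.158, 0.013, 0.055))
  expect_equal(unname(scn$matrix["moderate", ]), c(0.070, 0.501, 0.214, 0.215))
  expect_equal(unname(scn$matrix["severe", ]), c(0.001, 0.027, 0.492, 0.480))
  expect_equal(unname(scn$utilities), c(0.73, 0.69, 0.27, 0))
  expect_equal(unname(scn$reference$cost), c(3140, 9460, 16956, 0))
  expect_equal(scn$comparator$cost[["mild"]], 22000)
  expect_equal(scn$comparator$relative_risk, 0.6)
  expect_equal(wtp_threshold_from_gdp(scn$threshold_meta$gdp_per_capita,
                                      scn$threshold_meta$multiplier),
               scn$threshold)
})

test_that("schema violations are reported with the field path", {
  path <- system.file("extdata", "alzheimer.yaml", package = "ceamarkov")
  cfg <- yaml::read_yaml(path)
  cfg$utilities$moderate <- NULL
  broken <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, broken)
  expect_error(load_scenario(broken), "utilities\\.moderate")

  cfg <- yaml::read_yaml(path)
  cfg$transition_matrix$severe$death <- NULL
  yaml::write_yaml(cfg, broken)
  expect_error(load_scenario(broken), "transition_matrix\\.severe\\.death")

  cfg <- yaml::read_yaml(path)
  cfg$threshold <- NULL
  yaml::write_yaml(cfg, broken)
  expect_error(load_scenario(broken), "threshold")
})

test_that("scenarios round-trip through YAML", {
  scn <- alzheimer_scenario()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(scn, path)
  back <- load_scenario(path)
  expect_equal(unclass(back$matrix), unclass(scn$matrix), tolerance = 1e-9)
  expect_equal(back$utilities, scn$utilities, tolerance = 1e-9)
  expect_equal(back$reference$cost, scn$reference$cost, tolerance = 1e-9)
  expect_equal(back$comparator, scn$comparator, tolerance = 1e-9)
  expect_identical(back$conventions, scn$conventions)
  expect_equal(back$threshold, scn$threshold)
  expect_equal(back$ceac_grid, scn$ceac_grid)
})

test_that("strategy arms are assembled per the conventions", {
  scn <- alzheimer_scenario()
  arms <- build_strategies(scn)
  expect_equal(unclass(arms$reference$matrix), unclass(scn$matrix))
  expect_equal(unname(arms$comparator$matrix["mild", ]),
               c(0.967, 0, 0, 0.033), tolerance = 1e-12)
  expect_equal(arms$comparator$rewards$cost[["mild"]], 22000)
  # additive cost mode stacks the drug price on the reference care cost
  arms2 <- build_strategies(scn, list(comparator_cost_mode = "additive"))
  expect_equal(arms2$comparator$rewards$cost[["mild"]], 22000 + 3140)
  # utilities are shared between arms
  expect_equal(arms$comparator$rewards$utility, arms$reference$rewards$utility)
})

test_that("convention calibration enumerates the full grid and ranks by error", {
  scn <- alzheimer_scenario()
  cal <- calibrate_conventions(scn)
  expect_equal(nrow(cal), 36) # 3 RR x 3 timing x 2 discount x 2 cost modes
  expect_false(is.unsorted(cal$total_rel_error))
  best <- attr(cal, "best")
  # the shipped config freezes the winning combination
  expect_identical(best$rr_convention, scn$conventions$rr_convention)
  expect_identical(best$reward_timing, scn$conventions$reward_timing)
  expect_identical(best$apply_discount, scn$conventions$apply_discount)
  expect_identical(best$comparator_cost_mode,
                   scn$conventions$comparator_cost_mode)
  expect_error(calibrate_conventions(scn, targets = c(reference_cost = 1)),
               "calibration targets")
})

test_that("deterministic evaluation flags the comparator as not cost-effective", {
  res <- evaluate_scenario(alzheimer_scenario())
  expect_equal(res$comparison$status, "icer_defined")
  expect_gt(res$comparison$icer, 28617)
  expect_false(res$comparison$cost_effective)
  td <- tidy(res)
  expect_equal(nrow(td), 2)
  expect_equal(td$delta_cost[2], res$comparator$total_cost -
                 res$reference$total_cost, tolerance = 1e-12)
})
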