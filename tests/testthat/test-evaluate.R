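test_that("discount factors follow the first-year-undiscounted convention", {
  spec <- discount_spec(0.06)
  expect_equal(discount_factor(1, spec), 1)
  expect_equal(discount_factor(2, spec), 1 / 1.06, tolerance = 1e-12)
  expect_equal(discount_factor(5, spec), 1.06^-4, tolerance = 1e-12)
  expect_equal(discount_factor(3, discount_spec(0)), 1)
  # alternative convention: exponent equals the cycle number
  expect_equal(discount_factor(1, discount_spec(0.06, FALSE)), 1 / 1.06,
               tolerance = 1e-12)
  expect_error(discount_factor(0, spec), "cycle")
  expect_error(discount_spec(-0.01), "rate")
})

test_that("degenerate strategies accrue the obvious totals", {
  # zero rewards -> zero cost
  m <- table1_matrix()
  zero <- strategy("free", m, state_rewards(soc_costs * 0, ad_utilities))
  ev <- evaluate_strategy(zero, 1000, horizon = 5)
  expect_equal(ev$total_cost, 0)

  # cohort stuck forever in its entry state with utility 1 and cost 100
  # per year over 3 undiscounted cycles
  id <- transition_matrix(rbind(alive = c(alive = 1, gone = 0),
                                gone = c(alive = 0, gone = 1)),
                          absorbing = "gone")
  stuck <- strategy("stuck", id,
                    state_rewards(c(alive = 100, gone = 0),
                                  c(alive = 1, gone = 0)))
  ev <- evaluate_strategy(stuck, 10, horizon = 3, entry_state = "alive",
                          discount = discount_spec(0), timing = "begin")
  expect_equal(ev$total_qaly, 3)
  expect_equal(ev$total_cost, 300)
})

test_that("undiscounted begin-of-cycle SoC accrual matches the hand trace", {
  ev <- evaluate_strategy(soc_strategy(), 1000, horizon = 5,
                          discount = discount_spec(0), timing = "begin")
  expect_equal(ev$total_qaly, 2.950088, tolerance = 1e-4)
  expect_equal(ev$total_cost, 21034.18, tolerance = 1e-4)
})

test_that("totals equal the sum of the per-cycle table and scale invariance holds", {
  for (size in c(1, 1000, 1e5)) {
    ev <- evaluate_strategy(soc_strategy(), size, horizon = 5,
                            discount = discount_spec(0.06), timing = "half")
    expect_equal(ev$total_cost, sum(ev$per_cycle$cost), tolerance = 1e-9)
    expect_equal(ev$total_qaly, sum(ev$per_cycle$qaly), tolerance = 1e-9)
    expect_equal(ev$per_cycle$cohort_cost, ev$per_cycle$cost * size,
                 tolerance = 1e-9)
  }
  ev1 <- evaluate_strategy(soc_strategy(), 1, horizon = 5)
  ev2 <- evaluate_strategy(soc_strategy(), 1e5, horizon = 5)
  expect_equal(ev1$total_cost, ev2$total_cost, tolerance = 1e-12)
  expect_equal(ev1$total_qaly, ev2$total_qaly, tolerance = 1e-12)
})

test_that("discounted totals are non-increasing in the discount rate", {
  rates <- seq(0, 0.09, by = 0.01)
  totals <- vapply(rates, function(r) {
    ev <- evaluate_strategy(soc_strategy(), 1000, horizon = 5,
                            discount = discount_spec(r))
    c(ev$total_cost, ev$total_qaly)
  }, numeric(2))
  expect_true(all(diff(totals[1, ]) <= 0))
  expect_true(all(diff(totals[2, ]) <= 0))
})

test_that("incremental comparison reproduces the published increments", {
  ref <- fake_eval("SoC", 21292.16, 2.94)
  comp <- fake_eval("Aducanumab", 98068.49, 3.58)
  cmp <- compare_strategies(ref, comp, threshold = 28617)
  expect_equal(cmp$delta_cost, 76776.33, tolerance = 1e-9)
  expect_equal(cmp$delta_effect, 0.64, tolerance = 1e-9)
  expect_equal(cmp$status, "icer_defined")
  expect_equal(cmp$icer, cmp$delta_cost / cmp$delta_effect, tolerance = 1e-12)
  expect_false(cmp$cost_effective)
})

test_that("dominance and undefined verdicts are classified correctly", {
  base <- fake_eval("a", 100, 2)
  expect_equal(compare_strategies(base, fake_eval("b", 90, 3), 100)$status,
               "dominant")
  expect_true(compare_strategies(base, fake_eval("b", 90, 3), 100)$cost_effective)
  expect_equal(compare_strategies(base, fake_eval("b", 150, 1), 100)$status,
               "dominated")
  undef <- compare_strategies(base, fake_eval("b", 150, 2), 100)
  expect_equal(undef$status, "undefined")
  expect_true(is.na(undef$icer))
  expect_equal(compare_strategies(base, fake_eval("b", 110, 4), 100)$icer, 5)
})

test_that("NMB, ICER and the threshold rule agree algebraically", {
  expect_equal(net_monetary_benefit(76776.33, 0.64, 28617), -58461.45,
               tolerance = 1e-9)
  expect_equal(net_monetary_benefit(10, 2, 0), -10)
  expect_equal(net_monetary_benefit(10, 0, 99), -10)
  expect_error(net_monetary_benefit(1, 1, -5), "threshold")

  set.seed(11)
  for (i in 1:200) {
    dc <- stats::runif(1, -5e4, 1e5)
    de <- stats::runif(1, 1e-3, 1)      # positive incremental effect
    thr <- stats::runif(1, 0, 2e5)
    cmp <- compare_strategies(fake_eval("r", 0, 0), fake_eval("c", dc, de), thr)
    nmb <- net_monetary_benefit(dc, de, thr)
    acceptable <- if (cmp$status == "dominant") TRUE else cmp$icer <= thr
    expect_equal(cmp$cost_effective, nmb >= 0)
    expect_equal(acceptable, nmb >= 0)
  }
})

test_that("threshold derivation from GDP multiples", {
  expect_equal(wtp_threshold_from_gdp(9539, 3), 28617)
  expect_equal(wtp_threshold_from_gdp(5000, 1), 5000)
  expect_error(wtp_threshold_from_gdp(-1), "positive")
})

test_that("reward invariants are enforced", {
  expect_error(state_rewards(c(a = -1, b = 0), c(a = 0.5, b = 0)),
               "non-negative")
  expect_error(state_rewards(c(a = 1, b = 0), c(a = 1.5, b = 0)),
               "\\[0, 1\\]")
  m <- table1_matrix()
  bad_util <- ad_utilities
  bad_util["death"] <- 0.2
  expect_error(strategy("x", m, state_rewards(soc_costs, bad_util)),
               "absorbing")
})
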