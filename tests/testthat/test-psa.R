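test_that("method-of-moments beta parameters are exact", {
  # variance 1/12 at mean 1/2 is the uniform distribution
  expect_equal(parameterize_beta(0.5, sqrt(1 / 12)),
               c(alpha = 1, beta = 1), tolerance = 1e-12)
  ab <- parameterize_beta(0.73, 0.073)
  mean_back <- ab["alpha"] / sum(ab)
  var_back <- prod(ab) / (sum(ab)^2 * (sum(ab) + 1))
  expect_equal(unname(mean_back), 0.73, tolerance = 1e-12)
  expect_equal(unname(var_back), 0.073^2, tolerance = 1e-12)
  expect_error(parameterize_beta(0.73, 0.5), "infeasible")
  expect_error(parameterize_beta(1.2, 0.1), "mean")
})

test_that("method-of-moments gamma parameters are exact", {
  g <- parameterize_gamma(22000, 4400)
  expect_equal(g, c(shape = 25, scale = 880), tolerance = 1e-12)
  expect_equal(unname(g["shape"] * g["scale"]), 22000)
  expect_error(parameterize_gamma(-1, 1), "positive")
  expect_error(parameterize_gamma(1, 0), "positive")
})

test_that("sampled distributions recover the requested means (Monte Carlo)", {
  withr::with_seed(2024, {
    n <- 1e5
    ab <- parameterize_beta(0.73, 0.073)
    draws <- stats::rbeta(n, ab["alpha"], ab["beta"])
    expect_lt(abs(mean(draws) - 0.73), 3 * 0.073 / sqrt(n))
    g <- parameterize_gamma(22000, 4400)
    draws <- stats::rgamma(n, shape = g["shape"], scale = g["scale"])
    expect_lt(abs(mean(draws) - 22000), 3 * 4400 / sqrt(n))
  })
})

test_that("zero uncertainty collapses the cloud onto the base case", {
  scn <- alzheimer_scenario()
  scn$psa$uncertainty <- list(cost = 0, utility = 0, transition = 0)
  cloud <- run_psa(scn, n_iterations = 10, seed = 5)
  base <- evaluate_scenario(scn)$comparison
  expect_equal(unique(cloud$delta_cost), base$delta_cost, tolerance = 1e-12)
  expect_equal(unique(cloud$delta_effect), base$delta_effect,
               tolerance = 1e-12)
})

test_that("tiny uncertainty keeps the cloud centroid at the base case", {
  scn <- alzheimer_scenario()
  scn$psa$uncertainty <- list(cost = 1e-6, utility = 1e-6, transition = 1e-6)
  cloud <- run_psa(scn, n_iterations = 50, seed = 5)
  base <- evaluate_scenario(scn)$comparison
  expect_equal(mean(cloud$delta_cost), base$delta_cost, tolerance = 1e-4)
  expect_equal(mean(cloud$delta_effect), base$delta_effect, tolerance = 1e-4)
})

test_that("clouds are reproducible given the seed", {
  scn <- alzheimer_scenario()
  c1 <- run_psa(scn, 40, seed = 9)
  c2 <- run_psa(scn, 40, seed = 9)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  c3 <- run_psa(scn, 40, seed = 10)
  expect_false(identical(c1$delta_cost, c3$delta_cost))
  # different seeds agree in distribution (loose check on the centroid)
  expect_equal(mean(c1$delta_cost), mean(c3$delta_cost),
               tolerance = 0.1)
})

test_that("whole-row draws stay row-stochastic with the right means", {
  row <- c(mild = 0.774, moderate = 0.158, severe = 0.013, death = 0.055)
  withr::with_seed(3, {
    draws <- t(replicate(4000, ceamarkov:::sample_stochastic_row(row, 0.1)))
  })
  expect_true(all(abs(rowSums(draws) - 1) < 1e-12))
  expect_true(all(draws >= 0))
  # component means match the base row (3 SE of the dirichlet sd)
  k <- 1 / 0.1^2 - 1
  sds <- sqrt(row * (1 - row) / (k + 1))
  expect_true(all(abs(colMeans(draws) - row) < 3 * sds / sqrt(4000)))
  # structural zeros stay zero
  row0 <- c(a = 0.6, b = 0, c = 0.4)
  expect_true(all(replicate(50, ceamarkov:::sample_stochastic_row(row0, 0.2)["b"]) == 0))
})

test_that("the acceptability curve is a proper probability curve", {
  cloud <- tibble::tibble(delta_cost = c(10, 20, 30),
                          delta_effect = c(1, 2, 3))
  # zero threshold with all costs positive: nothing acceptable
  expect_equal(ceac(cloud, c(0, 1))$probability_acceptable[1], 0)
  # huge threshold with all effects positive: everything acceptable
  curve <- ceac(cloud, c(0, 5, 1e6))
  expect_equal(curve$probability_acceptable[3], 1)
  expect_false(is.unsorted(curve$probability_acceptable))
  expect_error(ceac(cloud[0, ], c(0, 1)), "empty")
  expect_error(ceac(cloud, c(5, 1)), "ascending")
})

test_that("CEAC is non-decreasing when every draw gains effectiveness", {
  scn <- alzheimer_scenario()
  cloud <- run_psa(scn, 200, seed = 17)
  expect_true(all(cloud$delta_effect > 0))
  curve <- ceac(cloud, scn$ceac_grid)
  expect_false(is.unsorted(curve$probability_acceptable))
})
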