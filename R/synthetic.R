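#' Blueprint for a random synthetic scenario
#'
#' Controls the structure of scenarios produced by [generate_scenario()]:
#' number of states (the last is an absorbing terminal state), whether
#' costs/utilities are ordered by disease severity, and cohort settings.
#' Generation is deterministic given `seed`.
#'
#' @param n_states Number of states, at least 2; the last is absorbing.
#' @param progression_ordering If `TRUE`, generated utilities are
#'   non-increasing and reference costs non-decreasing with severity.
#' @param seed Integer RNG seed.
#' @param horizon,cohort_size Cohort settings.
#' @return A `scenario_blueprint` object.
#' @export
scenario_blueprint <- function(n_states = 4L, progression_ordering = TRUE,
                               seed = 1L, horizon = 5L, cohort_size = 1000) {
  if (n_states < 2) stop("n_states must be at least 2", call. = FALSE)
  structure(list(n_states = as.integer(n_states),
                 progression_ordering = isTRUE(progression_ordering),
                 seed = as.integer(seed), horizon = as.integer(horizon),
                 cohort_size = cohort_size),
            class = "scenario_blueprint")
}

#' Generate a random valid scenario
#'
#' Draws a full two-arm scenario with the statistical structure the
#' analysis assumes: a row-stochastic matrix whose non-absorbing rows are
#' symmetric unit-sum random vectors, an absorbing terminal state,
#' utilities in \[0, 1\] (zero in the terminal state), positive reference
#' costs, a comparator arm that replaces the entry-state cost with a
#' higher drug cost, a relative risk in (0, 1\], a random discount rate
#' and threshold. The result always passes [validate_transition_matrix()]
#' and the reward invariants, and is identical for identical seeds.
#'
#' @param blueprint A [scenario_blueprint()].
#' @return A [cea_scenario()].
#' @export
generate_scenario <- function(blueprint = scenario_blueprint()) {
  stopifnot(inherits(blueprint, "scenario_blueprint"))
  n <- blueprint$n_states
  withr::with_seed(blueprint$seed, {
    lab <- c(paste0("stage_", seq_len(n - 1)), "death")
    p <- matrix(0, n, n, dimnames = list(lab, lab))
    for (i in seq_len(n - 1)) {
      g <- stats::rgamma(n, shape = 1)
      p[i, ] <- g / sum(g)
    }
    p[n, n] <- 1
    m <- transition_matrix(p, absorbing = "death")

    u <- stats::runif(n - 1, 0.05, 0.95)
    cost <- stats::runif(n - 1, 500, 20000)
    if (blueprint$progression_ordering) {
      u <- sort(u, decreasing = TRUE)
      cost <- sort(cost)
    }
    utilities <- stats::setNames(c(u, 0), lab)
    ref_cost <- stats::setNames(c(cost, 0), lab)
    comp_cost <- ref_cost
    comp_cost[1] <- ref_cost[1] + stats::runif(1, 1000, 30000)

    cea_scenario(
      name = sprintf("synthetic-%d-states-seed-%d", n, blueprint$seed),
      matrix = m,
      utilities = utilities,
      reference = list(name = "SoC", cost = ref_cost),
      comparator = list(name = "DMT", cost = comp_cost,
                        relative_risk = stats::runif(1, 0.2, 1),
                        source_state = lab[1]),
      conventions = list(
        rr_convention = sample(c("scale_all_exits", "progression_only"), 1),
        reward_timing = "begin",
        apply_discount = TRUE,
        comparator_cost_mode = "replace"),
      discount = list(rate = stats::runif(1, 0, 0.09),
                      range = c(0.03, 0.09),
                      first_cycle_undiscounted = TRUE),
      threshold = stats::runif(1, 10000, 100000),
      entry_state = lab[1],
      cohort_size = blueprint$cohort_size,
      horizon = blueprint$horizon
    )
  })
}

#' Individual-level microsimulation oracle
#'
#' Simulates each individual's state path by categorical draws from the
#' transition-matrix rows and accrues rewards with the identical timing
#' and discounting conventions as the cohort engine. By the law of large
#' numbers the sample means converge to [evaluate_strategy()]'s
#' expected-value results; the returned standard errors quantify the
#' Monte-Carlo error, so the microsimulation serves as an independent
#' check of the cohort-expectation arithmetic.
#'
#' @param scenario A [cea_scenario()].
#' @param arm `"reference"` or `"comparator"`.
#' @param n_individuals Number of simulated individuals.
#' @param seed Integer RNG seed.
#' @param conventions Optional convention overrides.
#' @return A one-row tibble: `arm`, `n`, per-person discounted
#'   `cost`/`qaly` sample means and standard errors.
#' @export
microsimulate <- function(scenario, arm = c("reference", "comparator"),
                          n_individuals, seed = 1L, conventions = NULL) {
  stopifnot(inherits(scenario, "cea_scenario"), n_individuals >= 1)
  arm <- match.arg(arm)
  conv <- validate_conventions(
    utils::modifyList(scenario$conventions, conventions %||% list()))
  strat <- build_strategies(scenario, conv)[[arm]]
  dsp <- scenario_discount_spec(scenario, conv)
  p <- unclass(strat$matrix)
  lab <- states(strat$matrix)
  n_s <- length(lab)
  cost_vec <- strat$rewards$cost[lab]
  util_vec <- strat$rewards$utility[lab]
  entry <- match(scenario$entry_state, lab)

  withr::with_seed(seed, {
    cur <- rep.int(entry, n_individuals)
    cost_acc <- numeric(n_individuals)
    qaly_acc <- numeric(n_individuals)
    for (t in seq_len(scenario$horizon)) {
      df <- discount_factor(t, dsp)
      nxt <- cur
      for (s in unique(cur)) {
        idx <- which(cur == s)
        nxt[idx] <- sample.int(n_s, length(idx), replace = TRUE,
                               prob = p[s, ])
      }
      w_cost <- switch(conv$reward_timing,
                       begin = cost_vec[cur],
                       end = cost_vec[nxt],
                       half = (cost_vec[cur] + cost_vec[nxt]) / 2)
      w_qaly <- switch(conv$reward_timing,
                       begin = util_vec[cur],
                       end = util_vec[nxt],
                       half = (util_vec[cur] + util_vec[nxt]) / 2)
      cost_acc <- cost_acc + w_cost * df
      qaly_acc <- qaly_acc + w_qaly * df
      cur <- nxt
    }
    tibble::tibble(
      arm = strat$name,
      n = n_individuals,
      cost = mean(cost_acc),
      cost_se = stats::sd(cost_acc) / sqrt(n_individuals),
      qaly = mean(qaly_acc),
      qaly_se = stats::sd(qaly_acc) / sqrt(n_individuals)
    )
  })
}
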