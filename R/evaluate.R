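#' Per-state annual rewards (costs and utilities)
#'
#' @param cost Named numeric vector: annual cost in USD per person-year in
#'   each state; all non-negative.
#' @param utility Named numeric vector over the same states: utility
#'   weight per year in \[0, 1\].
#' @return A `state_rewards` object.
#' @export
state_rewards <- function(cost, utility) {
  if (is.null(names(cost)) || is.null(names(utility))) {
    stop("cost and utility must be named by state", call. = FALSE)
  }
  if (!setequal(names(cost), names(utility))) {
    stop("cost and utility must cover the same states", call. = FALSE)
  }
  utility <- utility[names(cost)]
  if (any(cost < 0)) stop("costs must be non-negative", call. = FALSE)
  if (any(utility < 0 | utility > 1)) {
    stop("utilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(cost = cost, utility = utility), class = "state_rewards")
}

#' Bundle a named strategy arm
#'
#' A strategy couples a (possibly treatment-effect-adjusted) transition
#' matrix with per-state rewards. Absorbing states must carry zero cost
#' and zero utility.
#'
#' @param name Strategy label (e.g. `"SoC"`, `"Aducanumab"`).
#' @param matrix A valid [transition_matrix()].
#' @param rewards A [state_rewards()] covering every state of `matrix`.
#' @return A `cea_strategy` object.
#' @export
strategy <- function(name, matrix, rewards) {
  stopifnot(inherits(rewards, "state_rewards"))
  validate_transition_matrix(matrix)
  if (!setequal(names(rewards$cost), states(matrix))) {
    stop("rewards must be defined for every state of the matrix",
         call. = FALSE)
  }
  for (a in absorbing_states(matrix)) {
    if (rewards$cost[[a]] != 0 || rewards$utility[[a]] != 0) {
      stop("absorbing state '", a, "' must have zero cost and utility",
           call. = FALSE)
    }
  }
  structure(list(name = as.character(name), matrix = matrix,
                 rewards = rewards),
            class = "cea_strategy")
}

# shared accrual core: returns per-cycle discounted cohort cost/QALY
accrue_rewards <- function(m, cost, utility, cohort_size, horizon,
                           entry_state, timing, discount) {
  trace <- run_cohort(m, cohort_size, horizon, entry_state)
  occ <- trace_occupancy(trace)
  lab <- states(m)
  idx <- seq_len(horizon)
  w <- switch(timing,
              begin = occ[idx, , drop = FALSE],
              end   = occ[idx + 1, , drop = FALSE],
              half  = (occ[idx, , drop = FALSE] +
                       occ[idx + 1, , drop = FALSE]) / 2,
              stop("unknown reward timing '", timing, "'", call. = FALSE))
  df <- discount_factor(idx, discount)
  list(trace = trace,
       discount_factor = df,
       cohort_cost = as.numeric(w %*% cost[lab]) * df,
       cohort_qaly = as.numeric(w %*% utility[lab]) * df)
}

#' Evaluate a strategy: discounted costs and QALYs from a cohort trace
#'
#' Runs the cohort trace and accrues per-cycle cohort costs
#' (`sum(occupancy * annual_cost)`) and QALYs (`sum(occupancy * utility)`)
#' using begin-of-cycle, end-of-cycle, or half-cycle-corrected occupancy,
#' multiplied by the cycle's discount factor. Totals are reported per
#' person (cohort sums divided by `cohort_size`); the per-cycle table also
#' carries cohort totals.
#'
#' @param s A [strategy()].
#' @param cohort_size,horizon,entry_state Passed to [run_cohort()];
#'   `entry_state` defaults to the first state of the strategy's matrix.
#' @param discount A [discount_spec()].
#' @param timing Reward timing: `"begin"`, `"end"`, or `"half"`
#'   (half-cycle correction).
#' @return A `cea_eval` object with fields `strategy`, `total_cost`,
#'   `total_qaly` (per person) and a `per_cycle` tibble.
#' @seealso [compare_strategies()], [glance.cea_eval()]
#' @export
evaluate_strategy <- function(s, cohort_size = 1000, horizon = 5,
                              entry_state = states(s$matrix)[1],
                              discount = discount_spec(),
                              timing = c("begin", "end", "half")) {
  stopifnot(inherits(s, "cea_strategy"))
  timing <- match.arg(timing)
  acc <- accrue_rewards(s$matrix, s$rewards$cost, s$rewards$utility,
                        cohort_size, horizon, entry_state, timing, discount)
  per_cycle <- tibble::tibble(
    cycle = seq_len(horizon),
    discount_factor = acc$discount_factor,
    cohort_cost = acc$cohort_cost,
    cohort_qaly = acc$cohort_qaly,
    cost = acc$cohort_cost / cohort_size,
    qaly = acc$cohort_qaly / cohort_size
  )
  structure(
    list(strategy = s$name,
         total_cost = sum(per_cycle$cost),
         total_qaly = sum(per_cycle$qaly),
         per_cycle = per_cycle,
         trace = acc$trace,
         cohort_size = cohort_size,
         horizon = horizon,
         entry_state = entry_state,
         timing = timing,
         discount = discount),
    class = "cea_eval"
  )
}

#' @export
print.cea_eval <- function(x, ...) {
  cat(sprintf("<cea_eval> %s: per-person total cost $%.2f, total QALY %.4f (%d cycles)\n",
              x$strategy, x$total_cost, x$total_qaly, x$horizon))
  invisible(x)
}

#' Incremental comparison of two evaluated strategies
#'
#' Computes incremental cost and effectiveness of `comparator` over
#' `reference`, the ICER where defined, a dominance verdict, and
#' cost-effectiveness at a willingness-to-pay threshold. When the
#' incremental effect is zero the ICER is undefined and reported as a
#' distinct verdict, never as division output.
#'
#' @param reference,comparator `cea_eval` objects on the same per-person
#'   basis.
#' @param threshold Willingness-to-pay threshold in USD per QALY.
#' @return A `cea_comparison` object with `delta_cost`, `delta_effect`,
#'   `icer`, `status` (one of `"dominant"`, `"dominated"`,
#'   `"icer_defined"`, `"undefined"`), `nmb` and `cost_effective`.
#' @export
compare_strategies <- function(reference, comparator, threshold) {
  stopifnot(inherits(reference, "cea_eval"), inherits(comparator, "cea_eval"))
  delta_cost <- comparator$total_cost - reference$total_cost
  delta_effect <- comparator$total_qaly - reference$total_qaly
  if (delta_cost < 0 && delta_effect > 0) {
    status <- "dominant"; icer <- NA_real_
  } else if (delta_cost > 0 && delta_effect < 0) {
    status <- "dominated"; icer <- NA_real_
  } else if (delta_effect == 0) {
    status <- "undefined"; icer <- NA_real_
  } else {
    status <- "icer_defined"; icer <- delta_cost / delta_effect
  }
  cost_effective <- status == "dominant" ||
    (status == "icer_defined" && delta_effect > 0 && icer <= threshold)
  structure(
    list(reference = reference$strategy,
         comparator = comparator$strategy,
         delta_cost = delta_cost,
         delta_effect = delta_effect,
         icer = icer,
         status = status,
         threshold = threshold,
         nmb = net_monetary_benefit(delta_cost, delta_effect, threshold),
         cost_effective = cost_effective),
    class = "cea_comparison"
  )
}

#' @export
print.cea_comparison <- function(x, ...) {
  cat(sprintf("<cea_comparison> %s vs %s\n", x$comparator, x$reference))
  cat(sprintf("  delta cost $%.2f, delta effect %.4f QALY\n",
              x$delta_cost, x$delta_effect))
  if (x$status == "icer_defined") {
    cat(sprintf("  ICER $%.2f/QALY (threshold $%.0f) -> %scost-effective\n",
                x$icer, x$threshold, if (x$cost_effective) "" else "NOT "))
  } else {
    cat("  verdict:", x$status, "\n")
  }
  invisible(x)
}

#' Net monetary benefit
#'
#' `threshold * delta_effect - delta_cost`; positive iff the comparator is
#' acceptable at that willingness-to-pay threshold. Vectorised.
#'
#' @param delta_cost Incremental cost (USD).
#' @param delta_effect Incremental effectiveness (QALY).
#' @param threshold Willingness-to-pay threshold (USD/QALY), non-negative.
#' @return Net monetary benefit in USD.
#' @export
net_monetary_benefit <- function(delta_cost, delta_effect, threshold) {
  if (any(threshold < 0)) stop("threshold must be non-negative", call. = FALSE)
  threshold * delta_effect - delta_cost
}

#' Willingness-to-pay threshold from GDP per capita
#'
#' The WHO rule of thumb sets the threshold at a small multiple (usually
#' 3) of GDP per capita.
#'
#' @param gdp_per_capita GDP per capita in USD, positive.
#' @param multiplier Dimensionless multiple (default 3).
#' @return Threshold in USD per QALY.
#' @examples
#' wtp_threshold_from_gdp(9539) # 28617
#' @export
wtp_threshold_from_gdp <- function(gdp_per_capita, multiplier = 3) {
  if (!is.numeric(gdp_per_capita) || any(gdp_per_capita <= 0)) {
    stop("gdp_per_capita must be positive", call. = FALSE)
  }
  if (!is.numeric(multiplier) || any(multiplier <= 0)) {
    stop("multiplier must be positive", call. = FALSE)
  }
  multiplier * gdp_per_capita
}
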