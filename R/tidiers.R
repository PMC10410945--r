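#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-cycle accrual table of an evaluated strategy
#'
#' @param x A `cea_eval` from [evaluate_strategy()].
#' @param ... Unused.
#' @return The per-cycle tibble (cycle, discount factor, cohort and
#'   per-person cost/QALY) with a `strategy` column.
#' @method tidy cea_eval
#' @export
tidy.cea_eval <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(strategy = x$strategy), x$per_cycle)
}

#' One-row summary of an evaluated strategy
#'
#' @inheritParams tidy.cea_eval
#' @return A one-row tibble with per-person totals and the evaluation
#'   settings.
#' @method glance cea_eval
#' @export
glance.cea_eval <- function(x, ...) {
  tibble::tibble(strategy = x$strategy, total_cost = x$total_cost,
                 total_qaly = x$total_qaly, cohort_size = x$cohort_size,
                 horizon = x$horizon, timing = x$timing,
                 discount_rate = x$discount$rate)
}

#' One-row summary of an incremental comparison
#'
#' @param x A `cea_comparison` from [compare_strategies()].
#' @param ... Unused.
#' @method glance cea_comparison
#' @export
glance.cea_comparison <- function(x, ...) {
  tibble::tibble(reference = x$reference, comparator = x$comparator,
                 delta_cost = x$delta_cost, delta_effect = x$delta_effect,
                 icer = x$icer, status = x$status, threshold = x$threshold,
                 nmb = x$nmb, cost_effective = x$cost_effective)
}

#' Summary table of a deterministic scenario evaluation
#'
#' One row per strategy with per-person totals, plus incremental cost,
#' incremental effectiveness, ICER and the cost-effectiveness decision on
#' the comparator row.
#'
#' @param x A `cea_result` from [evaluate_scenario()].
#' @param ... Unused.
#' @method tidy cea_result
#' @export
tidy.cea_result <- function(x, ...) {
  cmp <- x$comparison
  tibble::tibble(
    strategy = c(x$reference$strategy, x$comparator$strategy),
    total_cost = c(x$reference$total_cost, x$comparator$total_cost),
    total_qaly = c(x$reference$total_qaly, x$comparator$total_qaly),
    delta_cost = c(NA_real_, cmp$delta_cost),
    delta_effect = c(NA_real_, cmp$delta_effect),
    icer = c(NA_real_, cmp$icer),
    cost_effective = c(NA, cmp$cost_effective)
  )
}

#' @rdname tidy.cea_result
#' @method glance cea_result
#' @export
glance.cea_result <- function(x, ...) glance(x$comparison)

#' One-row summary of a PSA cloud
#'
#' @param x A `cea_psa` from [run_psa()].
#' @param ... Unused.
#' @return A one-row tibble with the iteration count, seed, cloud
#'   centroid and the probability of cost-effectiveness at the scenario
#'   threshold.
#' @method glance cea_psa
#' @export
glance.cea_psa <- function(x, ...) {
  thr <- attr(x, "threshold")
  tibble::tibble(
    n_iterations = attr(x, "n_iterations"),
    seed = attr(x, "seed"),
    mean_delta_cost = mean(x$delta_cost),
    mean_delta_effect = mean(x$delta_effect),
    threshold = thr,
    prob_cost_effective =
      mean(net_monetary_benefit(x$delta_cost, x$delta_effect, thr) >= 0)
  )
}
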