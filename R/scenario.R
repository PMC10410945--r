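#' Assemble a cost-effectiveness scenario
#'
#' A scenario bundles everything a two-arm Markov cohort cost-effectiveness
#' analysis needs: the state space and base (reference-arm) transition
#' matrix, shared per-state utilities, per-arm state costs, the comparator's
#' relative-risk treatment effect, discounting, horizon, cohort size,
#' willingness-to-pay threshold, evaluation conventions and probabilistic
#' sensitivity settings.
#'
#' @param name Scenario label.
#' @param matrix A valid [transition_matrix()] for the reference arm.
#' @param utilities Named numeric vector of per-state utility weights in
#'   \[0, 1\], shared by both arms; absorbing states must be 0.
#' @param reference List with `name` and `cost` (named numeric vector of
#'   annual per-state costs, USD).
#' @param comparator List with `name`, `cost` (named numeric vector; under
#'   cost mode `"replace"` the entry-state value is the full annual drug
#'   cost, under `"additive"` it is added on top of the reference cost) and
#'   `relative_risk` plus `source_state` of the treatment effect.
#' @param conventions List of evaluation conventions:
#'   `rr_convention` (see [treatment_effect()]), `reward_timing`
#'   (`"begin"`, `"end"`, `"half"`), `apply_discount` (logical), and
#'   `comparator_cost_mode` (`"replace"` or `"additive"`).
#' @param discount List with `rate`, optional `range` (length-2, for
#'   one-way sensitivity analysis) and `first_cycle_undiscounted`.
#' @param threshold Willingness-to-pay threshold, USD/QALY.
#' @param entry_state,cohort_size,horizon Cohort settings (see
#'   [run_cohort()]).
#' @param psa List with `n_iterations` and `uncertainty` scales (standard
#'   error as a fraction of the mean) for `cost`, `utility` and
#'   `transition` parameters.
#' @param ceac_grid Ascending numeric grid of thresholds for the
#'   cost-effectiveness acceptability curve.
#' @param threshold_meta Optional list (e.g. `gdp_per_capita`,
#'   `multiplier`) documenting how the threshold was derived.
#' @param calibration_targets Optional named numeric vector
#'   (`reference_cost`, `comparator_cost`, `reference_qaly`,
#'   `comparator_qaly`) of published base-case results used by
#'   [calibrate_conventions()].
#' @return A validated `cea_scenario` object.
#' @seealso [load_scenario()], [alzheimer_scenario()],
#'   [evaluate_scenario()]
#' @export
cea_scenario <- function(name, matrix, utilities, reference, comparator,
                         conventions, discount, threshold,
                         entry_state = states(matrix)[1],
                         cohort_size = 1000, horizon = 5,
                         psa = list(n_iterations = 1000,
                                    uncertainty = list(cost = 0.2,
                                                       utility = 0.1,
                                                       transition = 0.1)),
                         ceac_grid = seq(0, 150000, by = 500),
                         threshold_meta = NULL,
                         calibration_targets = NULL) {
  validate_transition_matrix(matrix)
  lab <- states(matrix)
  check_named_over_states <- function(x, what) {
    if (is.null(names(x)) || !setequal(names(x), lab)) {
      stop(what, " must be named over exactly the states: ",
           paste(lab, collapse = ", "), call. = FALSE)
    }
    x[lab]
  }
  utilities <- check_named_over_states(utilities, "utilities")
  reference$cost <- check_named_over_states(reference$cost, "reference$cost")
  comparator$cost <- check_named_over_states(comparator$cost, "comparator$cost")
  for (a in absorbing_states(matrix)) {
    if (utilities[[a]] != 0) {
      stop("absorbing state '", a, "' must have utility 0", call. = FALSE)
    }
  }
  if (!entry_state %in% lab) stop("unknown entry_state", call. = FALSE)
  conventions <- validate_conventions(conventions)
  # constructs must succeed
  treatment_effect(comparator$relative_risk, comparator$source_state,
                   conventions$rr_convention)
  if (is.null(discount$first_cycle_undiscounted)) {
    discount$first_cycle_undiscounted <- TRUE
  }
  discount_spec(discount$rate, discount$first_cycle_undiscounted)
  if (!is.numeric(threshold) || threshold < 0) {
    stop("threshold must be a non-negative USD/QALY value", call. = FALSE)
  }
  if (is.unsorted(ceac_grid, strictly = TRUE)) {
    stop("ceac_grid must be strictly ascending", call. = FALSE)
  }
  structure(
    list(name = name, matrix = matrix, utilities = utilities,
         reference = reference, comparator = comparator,
         conventions = conventions, discount = discount,
         threshold = threshold, entry_state = entry_state,
         cohort_size = cohort_size, horizon = horizon, psa = psa,
         ceac_grid = ceac_grid, threshold_meta = threshold_meta,
         calibration_targets = calibration_targets),
    class = "cea_scenario"
  )
}

validate_conventions <- function(conventions) {
  defaults <- list(rr_convention = "scale_all_exits",
                   reward_timing = "begin",
                   apply_discount = TRUE,
                   comparator_cost_mode = "replace")
  conventions <- utils::modifyList(defaults, conventions %||% list())
  stopifnot(
    conventions$rr_convention %in% c("scale_all_exits", "progression_only",
                                     "complete_arrest"),
    conventions$reward_timing %in% c("begin", "end", "half"),
    is.logical(conventions$apply_discount),
    conventions$comparator_cost_mode %in% c("replace", "additive")
  )
  conventions
}

#' @export
print.cea_scenario <- function(x, ...) {
  cat(sprintf("<cea_scenario> %s\n", x$name))
  cat(sprintf("  %d states (%s), entry '%s', cohort %d, horizon %d cycles\n",
              length(states(x$matrix)), paste(states(x$matrix), collapse = ", "),
              x$entry_state, x$cohort_size, x$horizon))
  cat(sprintf("  %s vs %s (RR %.2f, %s), threshold $%.0f/QALY\n",
              x$comparator$name, x$reference$name,
              x$comparator$relative_risk, x$conventions$rr_convention,
              x$threshold))
  invisible(x)
}

#' Build the two strategy arms of a scenario
#'
#' Applies the comparator's treatment effect to the base matrix and
#' resolves the comparator cost structure per the conventions.
#'
#' @param scenario A [cea_scenario()].
#' @param conventions Optional convention overrides (merged over
#'   `scenario$conventions`).
#' @return A list with elements `reference` and `comparator`, each a
#'   [strategy()].
#' @export
build_strategies <- function(scenario, conventions = NULL) {
  conv <- validate_conventions(
    utils::modifyList(scenario$conventions, conventions %||% list()))
  ref_cost <- scenario$reference$cost
  comp_cost <- scenario$comparator$cost
  src <- scenario$comparator$source_state
  if (conv$comparator_cost_mode == "additive") {
    comp_cost[src] <- comp_cost[src] + ref_cost[src]
  }
  eff <- treatment_effect(scenario$comparator$relative_risk, src,
                          conv$rr_convention)
  comp_matrix <- apply_treatment_effect(scenario$matrix, eff)
  list(
    reference = strategy(scenario$reference$name, scenario$matrix,
                         state_rewards(ref_cost, scenario$utilities)),
    comparator = strategy(scenario$comparator$name, comp_matrix,
                          state_rewards(comp_cost, scenario$utilities))
  )
}

scenario_discount_spec <- function(scenario, conv) {
  discount_spec(
    rate = if (isTRUE(conv$apply_discount)) scenario$discount$rate else 0,
    first_cycle_undiscounted =
      isTRUE(scenario$discount$first_cycle_undiscounted)
  )
}

#' Deterministic base-case evaluation of a scenario
#'
#' Evaluates both arms under the scenario's (or overridden) conventions
#' and compares them at the scenario's willingness-to-pay threshold.
#'
#' @inheritParams build_strategies
#' @return A `cea_result` list with `reference` and `comparator`
#'   [evaluate_strategy()] results, the `comparison`
#'   ([compare_strategies()]) and the conventions used.
#' @examples
#' \donttest{
#' res <- evaluate_scenario(alzheimer_scenario())
#' tidy(res)
#' }
#' @export
evaluate_scenario <- function(scenario, conventions = NULL) {
  stopifnot(inherits(scenario, "cea_scenario"))
  conv <- validate_conventions(
    utils::modifyList(scenario$conventions, conventions %||% list()))
  arms <- build_strategies(scenario, conv)
  dsp <- scenario_discount_spec(scenario, conv)
  ref <- evaluate_strategy(arms$reference, scenario$cohort_size,
                           scenario$horizon, scenario$entry_state,
                           dsp, conv$reward_timing)
  comp <- evaluate_strategy(arms$comparator, scenario$cohort_size,
                            scenario$horizon, scenario$entry_state,
                            dsp, conv$reward_timing)
  structure(
    list(scenario = scenario$name,
         reference = ref, comparator = comp,
         comparison = compare_strategies(ref, comp, scenario$threshold),
         conventions = conv),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("<cea_result> %s\n", x$scenario))
  print(tidy(x))
  invisible(x)
}

#' Calibrate evaluation conventions against published base-case results
#'
#' Enumerates the convention grid — RR convention (`scale_all_exits`,
#' `progression_only`, `complete_arrest`) x reward timing (`begin`, `end`,
#' `half`) x discount application (on, off) x comparator cost mode
#' (`replace`, `additive`) — evaluates both arms for each combination, and
#' ranks the combinations by total relative error against the published
#' base-case totals (reference cost/QALY, comparator cost/QALY).
#'
#' @param scenario A [cea_scenario()].
#' @param targets Named numeric vector with `reference_cost`,
#'   `comparator_cost`, `reference_qaly`, `comparator_qaly`; defaults to
#'   `scenario$calibration_targets`.
#' @return A tibble of all combinations with the evaluated totals, ICER
#'   and `total_rel_error`, sorted ascending by error, with the winning
#'   convention list in attribute `"best"`.
#' @export
calibrate_conventions <- function(scenario,
                                  targets = scenario$calibration_targets) {
  stopifnot(inherits(scenario, "cea_scenario"))
  needed <- c("reference_cost", "comparator_cost",
              "reference_qaly", "comparator_qaly")
  targets <- unlist(targets)
  if (!all(needed %in% names(targets))) {
    stop("calibration targets must name: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  grid <- tidyr::expand_grid(
    rr_convention = c("scale_all_exits", "progression_only",
                      "complete_arrest"),
    reward_timing = c("begin", "end", "half"),
    apply_discount = c(TRUE, FALSE),
    comparator_cost_mode = c("replace", "additive")
  )
  rows <- purrr::pmap(grid, function(rr_convention, reward_timing,
                                     apply_discount, comparator_cost_mode) {
    conv <- list(rr_convention = rr_convention,
                 reward_timing = reward_timing,
                 apply_discount = apply_discount,
                 comparator_cost_mode = comparator_cost_mode)
    res <- evaluate_scenario(scenario, conv)
    vals <- c(reference_cost = res$reference$total_cost,
              comparator_cost = res$comparator$total_cost,
              reference_qaly = res$reference$total_qaly,
              comparator_qaly = res$comparator$total_qaly)
    tibble::tibble(
      !!!vals,
      icer = res$comparison$icer,
      total_rel_error = sum(abs(vals - targets[needed]) / targets[needed])
    )
  })
  out <- dplyr::arrange(dplyr::bind_cols(grid, dplyr::bind_rows(rows)),
                        .data$total_rel_error)
  best <- as.list(out[1, c("rr_convention", "reward_timing",
                           "apply_discount", "comparator_cost_mode")])
  structure(out, best = best,
            class = c("cea_calibration", class(out)))
}
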