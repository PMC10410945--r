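#' Default one-way sensitivity parameter set for a scenario
#'
#' Builds the parameter table varied by [one_way_dsa()]: per-state annual
#' costs (shared care costs vary in both arms together; arm-specific
#' costs, such as the drug price, vary alone), per-state utilities,
#' every non-zero off-diagonal transition probability of the base matrix,
#' and the discount rate. Ranges default to +/- `n_se` standard errors
#' around the base value, with the standard error taken as the scenario's
#' PSA uncertainty scale times the mean; the discount-rate range is the
#' scenario's stated range.
#'
#' @param scenario A [cea_scenario()].
#' @param n_se Half-width of the range in standard errors (default 1.96,
#'   a 95% interval).
#' @return A tibble with columns `parameter`, `type`, `strategy`, `state`,
#'   `from`, `to`, `base`, `low`, `high`.
#' @export
dsa_parameters <- function(scenario, n_se = 1.96) {
  stopifnot(inherits(scenario, "cea_scenario"))
  u_scale <- scenario$psa$uncertainty
  lab <- states(scenario$matrix)
  live <- setdiff(lab, absorbing_states(scenario$matrix))
  rows <- list()

  ref_cost <- scenario$reference$cost
  comp_cost <- scenario$comparator$cost
  shared <- live[ref_cost[live] == comp_cost[live] & ref_cost[live] > 0]
  for (s in shared) {
    b <- ref_cost[[s]]
    rows[[length(rows) + 1]] <- tibble::tibble(
      parameter = paste0("cost_", s), type = "cost", strategy = "shared",
      state = s, from = NA_character_, to = NA_character_,
      base = b, low = b * (1 - n_se * u_scale$cost),
      high = b * (1 + n_se * u_scale$cost))
  }
  for (arm in c("reference", "comparator")) {
    cost <- if (arm == "reference") ref_cost else comp_cost
    own <- setdiff(live[cost[live] > 0], shared)
    for (s in own) {
      b <- cost[[s]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        parameter = paste0("cost_", scenario[[arm]]$name, "_", s),
        type = "cost", strategy = arm, state = s,
        from = NA_character_, to = NA_character_,
        base = b, low = b * (1 - n_se * u_scale$cost),
        high = b * (1 + n_se * u_scale$cost))
    }
  }
  for (s in live[scenario$utilities[live] > 0]) {
    b <- scenario$utilities[[s]]
    rows[[length(rows) + 1]] <- tibble::tibble(
      parameter = paste0("utility_", s), type = "utility",
      strategy = "shared", state = s, from = NA_character_, to = NA_character_,
      base = b, low = max(0, b * (1 - n_se * u_scale$utility)),
      high = min(1, b * (1 + n_se * u_scale$utility)))
  }
  for (from in live) {
    for (to in setdiff(lab, from)) {
      b <- scenario$matrix[from, to]
      if (b <= 0) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        parameter = paste0("p_", from, "_", to), type = "transition",
        strategy = "shared", state = NA_character_, from = from, to = to,
        base = b, low = max(0, b * (1 - n_se * u_scale$transition)),
        high = min(1, b * (1 + n_se * u_scale$transition)))
    }
  }
  rng <- scenario$discount$range %||% c(0.03, 0.09)
  rows[[length(rows) + 1]] <- tibble::tibble(
    parameter = "discount_rate", type = "discount_rate",
    strategy = "shared", state = NA_character_,
    from = NA_character_, to = NA_character_,
    base = scenario$discount$rate, low = rng[1], high = rng[2])
  dplyr::bind_rows(rows)
}

# return a copy of the scenario with one parameter set to `value`
perturb_scenario <- function(scenario, param, value) {
  if (param$type == "utility") {
    scenario$utilities[[param$state]] <- value
  } else if (param$type == "cost") {
    if (param$strategy %in% c("shared", "reference")) {
      scenario$reference$cost[[param$state]] <- value
    }
    if (param$strategy %in% c("shared", "comparator")) {
      scenario$comparator$cost[[param$state]] <- value
    }
  } else if (param$type == "transition") {
    p <- unclass(scenario$matrix)
    delta <- value - p[param$from, param$to]
    p[param$from, param$to] <- value
    p[param$from, param$from] <- p[param$from, param$from] - delta
    scenario$matrix <- transition_matrix(
      p, absorbing = absorbing_states(scenario$matrix))
  } else if (param$type == "discount_rate") {
    scenario$discount$rate <- value
  } else {
    stop("unknown parameter type '", param$type, "'", call. = FALSE)
  }
  scenario
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-evaluates the incremental comparison with each parameter set to its
#' low and high value, all others at base, and records the two ICERs.
#' Varying a transition probability re-balances its row through the
#' origin state's self-transition (the row must remain valid). The
#' discount-rate entry evaluates with discounting enabled at the low and
#' high rates, so the parameter is informative even when the base case is
#' undiscounted.
#'
#' @param scenario A [cea_scenario()].
#' @param parameters A parameter table as built by [dsa_parameters()].
#' @return A `cea_tornado` tibble (`parameter`, `type`, `base`, `low`,
#'   `high`, `icer_low`, `icer_high`, `spread`), sorted descending by
#'   `spread`, with the base-case ICER in attribute `"icer_base"`.
#' @export
one_way_dsa <- function(scenario, parameters = dsa_parameters(scenario)) {
  stopifnot(inherits(scenario, "cea_scenario"))
  base_res <- evaluate_scenario(scenario)
  icer_at <- function(param, value) {
    sc <- perturb_scenario(scenario, param, value)
    conv <- NULL
    if (param$type == "discount_rate") conv <- list(apply_discount = TRUE)
    evaluate_scenario(sc, conv)$comparison$icer
  }
  out <- purrr::map_dfr(seq_len(nrow(parameters)), function(i) {
    param <- as.list(parameters[i, ])
    lo <- icer_at(param, param$low)
    hi <- icer_at(param, param$high)
    tibble::tibble(parameter = param$parameter, type = param$type,
                   base = param$base, low = param$low, high = param$high,
                   icer_low = lo, icer_high = hi,
                   spread = abs(hi - lo))
  })
  out <- dplyr::arrange(out, dplyr::desc(.data$spread))
  structure(out, icer_base = base_res$comparison$icer,
            class = c("cea_tornado", class(out)))
}
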