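#' Method-of-moments beta parameters
#'
#' Inverts the beta mean/variance relations: with
#' `nu = mean * (1 - mean) / se^2 - 1`, `alpha = mean * nu` and
#' `beta = (1 - mean) * nu`. The resulting distribution has exactly the
#' requested mean and standard deviation.
#'
#' @param mean Mean in (0, 1).
#' @param se Standard deviation; must satisfy `se^2 < mean * (1 - mean)`.
#' @return Named numeric vector `c(alpha, beta)`.
#' @examples
#' parameterize_beta(0.5, sqrt(1 / 12)) # uniform: alpha = beta = 1
#' @export
parameterize_beta <- function(mean, se) {
  if (!is.numeric(mean) || mean <= 0 || mean >= 1) {
    stop("mean must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(se) || se <= 0) stop("se must be positive", call. = FALSE)
  if (se^2 >= mean * (1 - mean)) {
    stop(sprintf(
      "variance %.4g infeasible for a beta distribution with mean %.4g",
      se^2, mean), call. = FALSE)
  }
  nu <- mean * (1 - mean) / se^2 - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Method-of-moments gamma parameters
#'
#' `shape = (mean / se)^2`, `scale = se^2 / mean`; the distribution has
#' exactly the requested mean and standard deviation.
#'
#' @param mean Mean, positive (e.g. an annual cost in USD).
#' @param se Standard deviation, positive.
#' @return Named numeric vector `c(shape, scale)`.
#' @examples
#' parameterize_gamma(22000, 4400) # shape 25, scale 880
#' @export
parameterize_gamma <- function(mean, se) {
  if (!is.numeric(mean) || mean <= 0) stop("mean must be positive", call. = FALSE)
  if (!is.numeric(se) || se <= 0) stop("se must be positive", call. = FALSE)
  c(shape = (mean / se)^2, scale = se^2 / mean)
}

# Dirichlet-style whole-row draw: component means equal `p`, concentration
# k = 1/scale^2 - 1; structural zeros stay zero. scale = 0 returns p.
sample_stochastic_row <- function(p, scale) {
  if (scale == 0) return(p)
  pos <- p > 0
  if (sum(pos) < 2) return(p)
  k <- 1 / scale^2 - 1
  g <- stats::rgamma(sum(pos), shape = p[pos] * k)
  if (sum(g) == 0) g[] <- p[pos] # vanishingly rare underflow guard
  out <- p
  out[pos] <- g / sum(g)
  out
}

# one Monte-Carlo draw of a scenario's uncertain quantities
sample_scenario_draw <- function(scenario) {
  u_scale <- scenario$psa$uncertainty
  lab <- states(scenario$matrix)
  live <- setdiff(lab, absorbing_states(scenario$matrix))

  p <- unclass(scenario$matrix)
  for (from in live) {
    p[from, ] <- sample_stochastic_row(p[from, ], u_scale$transition)
  }
  m <- transition_matrix(p, absorbing = absorbing_states(scenario$matrix))

  utils_draw <- scenario$utilities
  for (s in live) {
    u <- utils_draw[[s]]
    if (u > 0 && u < 1 && u_scale$utility > 0) {
      ab <- parameterize_beta(u, u_scale$utility * u)
      utils_draw[[s]] <- stats::rbeta(1, ab["alpha"], ab["beta"])
    }
  }

  draw_cost <- function(mean) {
    if (mean <= 0 || u_scale$cost == 0) return(mean)
    gp <- parameterize_gamma(mean, u_scale$cost * mean)
    stats::rgamma(1, shape = gp["shape"], scale = gp["scale"])
  }
  ref_cost <- scenario$reference$cost
  comp_cost <- scenario$comparator$cost
  for (s in lab) {
    drawn <- draw_cost(ref_cost[[s]])
    if (comp_cost[[s]] == ref_cost[[s]]) {
      # same literature parameter in both arms: share the draw
      ref_cost[[s]] <- drawn
      comp_cost[[s]] <- drawn
    } else {
      ref_cost[[s]] <- drawn
      comp_cost[[s]] <- draw_cost(comp_cost[[s]])
    }
  }
  list(matrix = m, utilities = utils_draw,
       reference_cost = ref_cost, comparator_cost = comp_cost)
}

#' Probabilistic sensitivity analysis (second-order Monte Carlo)
#'
#' Per iteration, draws utilities (beta), costs (gamma; care costs shared
#' between arms share one draw) and the non-absorbing transition rows
#' (whole-row draws that remain stochastic), all parameterised by method
#' of moments with standard errors equal to the scenario's uncertainty
#' scales times the means; rebuilds both strategies (the treatment effect
#' is applied to the sampled base matrix); evaluates both arms under the
#' scenario conventions; and stores the paired incremental cost and
#' effectiveness. Deterministic given `seed`.
#'
#' @param scenario A [cea_scenario()].
#' @param n_iterations Number of Monte-Carlo iterations.
#' @param seed Integer RNG seed (the global RNG state is left untouched).
#' @param conventions Optional convention overrides.
#' @return A `cea_psa` tibble with one row per iteration (`iteration`,
#'   per-arm per-person `cost`/`qaly`, `delta_cost`, `delta_effect`,
#'   `icer`), with attributes `seed`, `n_iterations` and `threshold`.
#' @seealso [ceac()], [plot_ce_plane()]
#' @export
run_psa <- function(scenario, n_iterations = scenario$psa$n_iterations,
                    seed = 1L, conventions = NULL) {
  stopifnot(inherits(scenario, "cea_scenario"), n_iterations >= 1)
  conv <- validate_conventions(
    utils::modifyList(scenario$conventions, conventions %||% list()))
  dsp <- scenario_discount_spec(scenario, conv)
  src <- scenario$comparator$source_state
  eff <- treatment_effect(scenario$comparator$relative_risk, src,
                          conv$rr_convention)
  totals <- function(m, cost, utility) {
    acc <- accrue_rewards(m, cost, utility, scenario$cohort_size,
                          scenario$horizon, scenario$entry_state,
                          conv$reward_timing, dsp)
    c(sum(acc$cohort_cost), sum(acc$cohort_qaly)) / scenario$cohort_size
  }
  draws <- withr::with_seed(seed, {
    purrr::map(seq_len(n_iterations), function(i) {
      d <- sample_scenario_draw(scenario)
      comp_cost <- d$comparator_cost
      if (conv$comparator_cost_mode == "additive") {
        comp_cost[src] <- comp_cost[src] + d$reference_cost[src]
      }
      comp_m <- apply_treatment_effect(d$matrix, eff)
      ref <- totals(d$matrix, d$reference_cost, d$utilities)
      comp <- totals(comp_m, comp_cost, d$utilities)
      c(ref, comp)
    })
  })
  mat <- do.call(rbind, draws)
  out <- tibble::tibble(
    iteration = seq_len(n_iterations),
    reference_cost = mat[, 1], reference_qaly = mat[, 2],
    comparator_cost = mat[, 3], comparator_qaly = mat[, 4],
    delta_cost = mat[, 3] - mat[, 1],
    delta_effect = mat[, 4] - mat[, 2]
  )
  out$icer <- ifelse(out$delta_effect == 0, NA_real_,
                     out$delta_cost / out$delta_effect)
  structure(out, seed = seed, n_iterations = n_iterations,
            threshold = scenario$threshold, conventions = conv,
            class = c("cea_psa", class(out)))
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value `lambda` on the grid, the probability
#' of acceptance is the fraction of PSA samples with non-negative net
#' monetary benefit, `lambda * delta_effect - delta_cost >= 0`.
#'
#' @param cloud A `cea_psa` tibble (or any data frame with `delta_cost`
#'   and `delta_effect` columns), non-empty.
#' @param thresholds Ascending numeric grid of thresholds (USD/QALY).
#' @return A `cea_ceac` tibble with columns `threshold` and
#'   `probability_acceptable`.
#' @export
ceac <- function(cloud, thresholds) {
  if (nrow(cloud) == 0) stop("empty PSA cloud", call. = FALSE)
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly ascending", call. = FALSE)
  }
  prob <- vapply(thresholds, function(lambda) {
    mean(net_monetary_benefit(cloud$delta_cost, cloud$delta_effect,
                              lambda) >= 0)
  }, numeric(1))
  structure(tibble::tibble(threshold = thresholds,
                           probability_acceptable = prob),
            class = c("cea_ceac", class(tibble::tibble())))
}
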