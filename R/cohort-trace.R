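#' Run a closed-cohort Markov trace
#'
#' Propagates a closed cohort through the state space for `horizon` annual
#' cycles: the full cohort starts in `entry_state` at cycle 0 and the
#' occupancy row vector is multiplied on the right by the transition
#' matrix once per cycle. Occupancy is tracked as expected fractional
#' persons (cohort expectation), not integer counts.
#'
#' @param m A valid [transition_matrix()].
#' @param cohort_size Number of persons in the cohort (default 1000).
#' @param horizon Number of cycles (years), at least 1.
#' @param entry_state Label of the state the cohort starts in (defaults to
#'   the first state).
#' @return A `cohort_trace` tibble with a `cycle` column (0..horizon) and
#'   one occupancy column per state, carrying `cohort_size`, `entry_state`
#'   and `states` attributes. Every row sums to `cohort_size` and the
#'   occupancy of absorbing states is non-decreasing.
#' @examples
#' m <- transition_matrix(rbind(
#'   mild  = c(mild = 0.9, death = 0.1),
#'   death = c(mild = 0,   death = 1)
#' ))
#' run_cohort(m, cohort_size = 1000, horizon = 3)
#' @export
run_cohort <- function(m, cohort_size = 1000, horizon, entry_state = states(m)[1]) {
  validate_transition_matrix(m)
  if (!is.numeric(horizon) || length(horizon) != 1 || horizon < 1 ||
      horizon != round(horizon)) {
    stop("horizon must be a positive whole number of cycles", call. = FALSE)
  }
  if (!is.numeric(cohort_size) || length(cohort_size) != 1 || cohort_size <= 0) {
    stop("cohort_size must be a positive count", call. = FALSE)
  }
  lab <- states(m)
  if (!entry_state %in% lab) {
    stop("unknown entry_state '", entry_state, "'", call. = FALSE)
  }
  occ <- matrix(0, nrow = horizon + 1, ncol = length(lab),
                dimnames = list(NULL, lab))
  occ[1, entry_state] <- cohort_size
  p <- unclass(m)
  for (t in seq_len(horizon)) {
    occ[t + 1, ] <- occ[t, ] %*% p
  }
  out <- dplyr::bind_cols(tibble::tibble(cycle = 0:horizon),
                          tibble::as_tibble(occ))
  structure(out,
            cohort_size = cohort_size,
            entry_state = entry_state,
            states = lab,
            class = c("cohort_trace", class(out)))
}

# occupancy matrix (cycles x states) of a cohort_trace
trace_occupancy <- function(trace) {
  as.matrix(trace[, attr(trace, "states"), drop = FALSE])
}
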