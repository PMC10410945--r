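#' Specify a relative-risk treatment effect on one transition row
#'
#' A disease-modifying therapy is modelled as a relative risk `RR` in
#' (0, 1\] applied to the outgoing transitions of one non-absorbing state
#' (for Alzheimer's disease, the mild state). Because the published
#' descriptions of how an RR is folded into a transition row differ, three
#' conventions are supported:
#'
#' * `"scale_all_exits"`: every exit probability from the source state
#'   (progression *and* death) is multiplied by `RR`; the self-transition
#'   is set to one minus their sum. This realises a reading in which the
#'   death transition from the source state is also decreased.
#' * `"progression_only"`: only transitions to worse, non-absorbing
#'   disease states are multiplied by `RR`; the death transition is left
#'   unchanged and the self-transition absorbs the freed probability.
#'   This is the standard epidemiological reading.
#' * `"complete_arrest"`: the best-case scenario in which the therapy
#'   completely arrests progression — all progression probabilities are
#'   zeroed, the death transition is multiplied by `RR`, and the
#'   self-transition takes the remainder.
#'
#' @param relative_risk Dimensionless ratio in (0, 1]; 1 means no effect.
#' @param source_state Label of the (non-absorbing) state whose outgoing
#'   row is adjusted.
#' @param convention One of `"scale_all_exits"`, `"progression_only"`,
#'   `"complete_arrest"`.
#' @return A `treatment_effect` object.
#' @seealso [apply_treatment_effect()]
#' @export
treatment_effect <- function(relative_risk,
                             source_state = "mild",
                             convention = c("scale_all_exits",
                                            "progression_only",
                                            "complete_arrest")) {
  convention <- match.arg(convention)
  if (!is.numeric(relative_risk) || length(relative_risk) != 1 ||
      is.na(relative_risk) || relative_risk <= 0 || relative_risk > 1) {
    stop("relative_risk must be a single number in (0, 1]", call. = FALSE)
  }
  structure(
    list(relative_risk = as.numeric(relative_risk),
         source_state = as.character(source_state),
         convention = convention),
    class = "treatment_effect"
  )
}

#' Apply a treatment effect to a transition matrix
#'
#' Returns a new valid transition matrix in which only the source state's
#' row differs from `m`, per the effect's convention (see
#' [treatment_effect()]). The adjusted row still sums to 1.
#'
#' @param m A valid [transition_matrix()].
#' @param effect A [treatment_effect()].
#' @return A validated `transition_matrix`.
#' @examples
#' m <- transition_matrix(rbind(
#'   mild     = c(mild = 0.774, moderate = 0.158, severe = 0.013, death = 0.055),
#'   moderate = c(0.070, 0.501, 0.214, 0.215),
#'   severe   = c(0.001, 0.027, 0.492, 0.480),
#'   death    = c(0, 0, 0, 1)
#' ))
#' apply_treatment_effect(m, treatment_effect(0.6, "mild", "scale_all_exits"))["mild", ]
#' @export
apply_treatment_effect <- function(m, effect) {
  stopifnot(inherits(effect, "treatment_effect"))
  validate_transition_matrix(m)
  src <- effect$source_state
  rr <- effect$relative_risk
  lab <- states(m)
  if (!src %in% lab) {
    stop("source_state '", src, "' is not in the state space", call. = FALSE)
  }
  if (src %in% absorbing_states(m)) {
    stop("source_state '", src, "' is absorbing; its row cannot be adjusted",
         call. = FALSE)
  }
  # RR = 1 is the exact identity for the scaling conventions
  if (rr == 1 && effect$convention != "complete_arrest") return(m)
  row <- m[src, ]
  exits <- setdiff(lab, src)
  if (effect$convention == "scale_all_exits") {
    row[exits] <- row[exits] * rr
    row[src] <- 1 - sum(row[exits])
  } else if (effect$convention == "progression_only") {
    pos <- match(src, lab)
    worse <- setdiff(lab[seq_along(lab) > pos], absorbing_states(m))
    row[worse] <- row[worse] * rr
    row[src] <- 1 - sum(row[exits])
  } else { # complete_arrest
    absorbed <- intersect(exits, absorbing_states(m))
    new_row <- stats::setNames(numeric(length(lab)), lab)
    new_row[absorbed] <- row[absorbed] * rr
    new_row[src] <- 1 - sum(new_row[absorbed])
    row <- new_row
  }
  out <- unclass(m)
  out[src, ] <- row
  transition_matrix(out, absorbing = absorbing_states(m))
}
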