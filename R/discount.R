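#' Discounting specification
#'
#' Annual discounting of costs and health outcomes. The conventional
#' reading of "discounted except the first year" leaves cycle 1
#' undiscounted and applies `(1 + rate)^-(cycle - 1)` thereafter; the
#' alternative convention discounts every cycle with exponent `cycle`.
#'
#' @param rate Annual discount rate as a fraction (e.g. 0.06); must be
#'   non-negative. A rate of 0 disables discounting.
#' @param first_cycle_undiscounted If `TRUE` (default) the discount
#'   exponent is `cycle - 1`, so the first cycle is undiscounted; if
#'   `FALSE` the exponent is `cycle`.
#' @return A `discount_spec` object.
#' @export
discount_spec <- function(rate = 0.06, first_cycle_undiscounted = TRUE) {
  if (!is.numeric(rate) || length(rate) != 1 || is.na(rate) || rate < 0) {
    stop("rate must be a single non-negative number", call. = FALSE)
  }
  structure(list(rate = as.numeric(rate),
                 first_cycle_undiscounted = isTRUE(first_cycle_undiscounted)),
            class = "discount_spec")
}

#' Discount factor for a cycle
#'
#' @param cycle 1-based cycle number(s); vectorised.
#' @param spec A [discount_spec()].
#' @return Dimensionless multiplier(s) in (0, 1].
#' @examples
#' discount_factor(1:5, discount_spec(0.06))
#' @export
discount_factor <- function(cycle, spec = discount_spec()) {
  stopifnot(inherits(spec, "discount_spec"))
  if (any(cycle < 1) || any(cycle != round(cycle))) {
    stop("cycle index must be a whole number >= 1", call. = FALSE)
  }
  expo <- if (spec$first_cycle_undiscounted) cycle - 1 else cycle
  (1 + spec$rate)^(-expo)
}
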